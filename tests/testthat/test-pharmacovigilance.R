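mk_report <- function(case, vdate, drug = "cyclosporine", role = "PS",
                      pt = NA_integer_, start = "2020-01-01",
                      event = "2020-03-01") {
  data.frame(case_number = case, version_date = as.Date(vdate),
             drug = drug, role_code = role, pt_code = pt,
             start_date = as.Date(start), end_date = as.Date(event) + 10,
             event_date = as.Date(event), stringsAsFactors = FALSE)
}

test_that("deduplication keeps the most recent report version per case", {
  reps <- rbind(mk_report("123", "2020-01-05", pt = 10047700L),
                mk_report("123", "2021-06-01", pt = 10028813L),
                mk_report("456", "2019-01-01"))
  out <- deduplicate_reports(reps)
  expect_equal(sort(unique(out$case_number)), c("123", "456"))
  expect_equal(out$pt_code[out$case_number == "123"], 10028813L)
  # no duplicates: identity
  solo <- mk_report("789", "2020-01-01")
  expect_equal(deduplicate_reports(solo), solo)
  # empty input, empty output
  expect_equal(nrow(deduplicate_reports(reps[0, ])), 0)
})

test_that("role-code and date filters exclude the stated cases with tallies", {
  reps <- rbind(mk_report("1", "2020-01-01"),                    # keep
                mk_report("2", "2020-01-01", role = "C"),        # role
                mk_report("3", "2020-01-01", role = "SS"),       # keep
                mk_report("4", "2020-01-01", start = "2020-05-01",
                          event = "2020-03-01"),                 # date error
                mk_report("5", "2020-01-01", role = "XX"))       # unknown
  expect_warning(fl <- apply_report_filters(reps, "cyclosporine"),
                 "unknown role")
  expect_equal(sort(unique(fl$reports$case_number)), c("1", "3"))
  expect_equal(fl$exclusions[["role_code"]], 1)
  expect_equal(fl$exclusions[["date_error"]], 1)
  expect_equal(fl$exclusions[["unknown_role"]], 1)
  expect_equal(fl$n_in - fl$n_out, sum(fl$exclusions))
})

test_that("contingency table reproduces planted cohort counts exactly", {
  spec <- report_cohort_spec(n_comparator = 800, n_exposed = 150,
                             event_rates = c("10072268" = 0.05,
                                             "10044565" = 0.1),
                             planted_or = c(4, 1),
                             dup_fraction = 0.15,
                             date_error_fraction = 0.05, seed = 42)
  tab <- generate_report_cohort(spec)
  truth <- attr(tab, "truth")
  dd <- deduplicate_reports(tab)
  # dedup restores exactly the constructed case count
  expect_equal(length(unique(dd$case_number)), 950)
  fl <- apply_report_filters(dd, c("cyclosporine", "voriconazole"))
  expect_equal(fl$exclusions[["date_error"]], attr(tab, "n_date_error"))
  for (j in seq_len(nrow(truth))) {
    ct <- contingency_table(fl$reports, c("cyclosporine", "voriconazole"),
                            "cyclosporine",
                            event_definition("ev", truth$pt_code[j]))
    expect_equal(c(ct$a, ct$b, ct$c, ct$d),
                 c(truth$a[j], truth$b[j], truth$c[j], truth$d[j]))
  }
})

test_that("contingency edge cases: absent events, unknown PT, overlap", {
  reps <- rbind(mk_report("1", "2020-01-01"),
                mk_report("2", "2020-01-01", drug = "voriconazole",
                          role = "SS"),
                mk_report("2", "2020-01-01"))
  ct <- contingency_table(reps, c("cyclosporine", "voriconazole"),
                          "cyclosporine",
                          event_definition("dili", 10072268L))
  expect_equal(ct$a + ct$c, 0)
  expect_warning(
    ct2 <- contingency_table(reps, c("cyclosporine", "voriconazole"),
                             "cyclosporine",
                             suppressWarnings(event_definition("x", 999L))),
    "unknown PT")
  expect_equal(ct2$a + ct2$c, 0)
  expect_error(contingency_table(reps, "cyclosporine", "cyclosporine",
                                 event_definition("dili", 10072268L)),
               "overlap")
})

test_that("ROR point estimate, CI and significance rule", {
  r <- reporting_odds_ratio(contingency_counts(25, 25, 25, 25))
  expect_equal(r$ror, 1)
  expect_false(r$significant)
  r2 <- reporting_odds_ratio(contingency_counts(10, 90, 100, 9900))
  expect_equal(r2$ror, 11)
  expect_true(r2$assessable)
  expect_true(r2$significant)                 # ci_low > 1
  expect_true(r2$ci_low <= r2$ror && r2$ror <= r2$ci_high)
  # Woolf CI by direct arithmetic
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r2$ci_low, exp(log(11) - 1.96 * se))
  expect_equal(r2$ci_high, exp(log(11) + 1.96 * se))
})

test_that("ROR invariances: row scaling and group swap", {
  base <- reporting_odds_ratio(contingency_counts(12, 188, 40, 960))
  scaled <- reporting_odds_ratio(contingency_counts(36, 564, 40, 960))
  expect_equal(scaled$ror, base$ror)
  swap <- reporting_odds_ratio(contingency_counts(40, 960, 12, 188))
  expect_equal(swap$ror, 1 / base$ror)
  expect_equal(swap$ci_low, 1 / base$ci_high)
})

test_that("empty exposure or zero cells are not assessable unless corrected", {
  r0 <- reporting_odds_ratio(contingency_counts(0, 0, 50, 950))
  expect_false(r0$assessable)
  expect_true(is.na(r0$ror))
  rz <- reporting_odds_ratio(contingency_counts(0, 174, 50, 950))
  expect_false(rz$assessable)
  rh <- reporting_odds_ratio(contingency_counts(0, 174, 50, 950),
                             correction = "haldane")
  expect_true(rh$assessable)
  expect_equal(rh$ror, (0.5 * 950.5) / (174.5 * 50.5))
  expect_error(reporting_odds_ratio(contingency_counts(1, 1, 1, 1)), NA)
})

test_that("ROR equals the univariate logistic regression on the same 2x2", {
  for (cells in list(c(3, 171, 10, 9134), c(9, 165, 108, 9036),
                     c(5, 169, 95, 9049), c(7, 13, 40, 160))) {
    r <- reporting_odds_ratio(do.call(contingency_counts, as.list(cells)))
    df <- data.frame(
      event = rep(c(1, 0, 1, 0), cells),
      exposed = rep(c(1, 1, 0, 0), cells))
    g <- stats::glm(event ~ exposed, family = stats::binomial(), data = df)
    expect_equal(r$ror, unname(exp(stats::coef(g)["exposed"])),
                 tolerance = 1e-6)
    p_wald <- summary(g)$coefficients["exposed", "Pr(>|z|)"]
    expect_equal(r$p_value, p_wald, tolerance = 1e-4)
  }
})

test_that("alternative p-value methods are labelled and plausible", {
  tab <- contingency_counts(9, 165, 108, 9036)
  pw <- reporting_odds_ratio(tab, p_method = "wald")
  pc <- suppressWarnings(reporting_odds_ratio(tab, p_method = "chisq"))
  pf <- reporting_odds_ratio(tab, p_method = "fisher")
  expect_equal(pw$p_method, "wald")
  expect_true(all(c(pw$p_value, pc$p_value, pf$p_value) < 0.05))
  expect_false(isTRUE(all.equal(pw$p_value, pc$p_value)))
})

test_that("pipeline is deterministic and order-fixed with additive tallies", {
  spec <- report_cohort_spec(n_comparator = 400, n_exposed = 100,
                             event_rates = c("10047700" = 0.1),
                             planted_or = 3, seed = 9)
  tab <- generate_report_cohort(spec)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  r1 <- ror_pipeline(read_reports(f), c("cyclosporine", "voriconazole"),
                     "cyclosporine",
                     list(event_definition("vomiting", 10047700L)))
  r2 <- ror_pipeline(read_reports(f), c("cyclosporine", "voriconazole"),
                     "cyclosporine",
                     list(event_definition("vomiting", 10047700L)))
  expect_identical(r1, r2)
  dd <- deduplicate_reports(tab)
  fl <- apply_report_filters(dd, "cyclosporine")
  expect_equal(fl$n_in - fl$n_out, sum(fl$exclusions))
})
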