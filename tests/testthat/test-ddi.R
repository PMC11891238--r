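# fast-equilibrating victim/perpetrator pair for scenario tests
fast_victim <- function()
  victim_disposition(test_params(fm_CYP3A4 = 0.8))
fast_perp <- function(CLint_h = 400)
  test_params(ka = 1.5, V1 = 40, k12 = 0.2, k21 = 0.2, CLint_h = CLint_h,
              CLr = 1, FaFg = 0.9, fu_b = 0.2, MW = 400)
vreg <- regimen_schedule(50, c(0, 12), cycle_length = 24)
preg <- regimen_schedule(100, 0, cycle_length = 24)

test_that("competitive inhibition of intrinsic clearance", {
  expect_equal(inhibited_intrinsic_clearance(254.19, 0, 5.48), 254.19)
  expect_equal(inhibited_intrinsic_clearance(254.19, 5.48, 5.48),
               254.19 / 2)
  expect_equal(inhibited_intrinsic_clearance(254.19, 0.06, 5.48),
               251.437039711, tolerance = 1e-9)
  iu <- seq(0, 50, 2)
  expect_true(all(diff(inhibited_intrinsic_clearance(100, iu, 5)) < 0))
  expect_error(inhibited_intrinsic_clearance(100, -1, 5), ">= 0")
  expect_error(inhibited_intrinsic_clearance(100, 1, 0), "Ki")
})

test_that("gut availability model has the stated bounds and algebra", {
  expect_equal(gut_availability(0.28, 1), 0.28)
  expect_equal(gut_availability(0.28, 0), 1)
  expect_equal(gut_availability(0.28, 0) / 0.28, 1 / 0.28)  # fg bound
  # equivalent flow-form parameterisation: Fg = Q/(Q + CLg), CLg scaled
  Fg <- 0.28; Q <- 18; CLg <- Q * (1 - Fg) / Fg
  expect_equal(gut_availability(Fg, 0.5), Q / (Q + 0.5 * CLg))
  expect_equal(gut_availability(0.28, 0.5), 0.4375)
  r <- seq(0, 1, 0.1)
  fg <- gut_availability(0.28, r)
  expect_true(all(fg >= 0.28 - 1e-12 & fg <= 1 + 1e-12))
  expect_error(gut_availability(0, 0.5), "Fg_base")
  expect_error(gut_availability(0.5, 1.2), "ratio")
})

test_that("static enterocyte concentration estimate is dimensionally sound", {
  expect_equal(gut_inhibitor_concentration(0, 1.51, 0.98, 437.47), 0)
  expect_equal(gut_inhibitor_concentration(200, 1.51, 0.98, 437.47),
               37.5847994656, tolerance = 1e-9)
  expect_equal(gut_inhibitor_concentration(400, 1.51, 0.98, 437.47),
               2 * gut_inhibitor_concentration(200, 1.51, 0.98, 437.47))
  expect_error(gut_inhibitor_concentration(200, 1.51, 0.98, -1), "MW")
})

test_that("no-inhibitor scenario returns ratios of exactly one", {
  r <- run_ddi_scenario(fast_victim(), vreg, fast_perp(), preg,
                        inhibition_spec(5, FALSE, FALSE), dt = 0.1)
  expect_identical(r$auc_ratio, 1)
  expect_identical(r$cmax_ratio, 1)
  expect_identical(r$fg_ratio, 1)
  expect_identical(r$hepatic_clearance_ratio, 1)
})

test_that("site toggles order exposure ratios as expected", {
  v <- fast_victim(); p <- fast_perp()
  liver <- run_ddi_scenario(v, vreg, p, preg,
                            inhibition_spec(2, FALSE, TRUE), dt = 0.1)
  both <- run_ddi_scenario(v, vreg, p, preg,
                           inhibition_spec(2, TRUE, TRUE), dt = 0.1)
  gut <- run_ddi_scenario(v, vreg, p, preg,
                          inhibition_spec(2, TRUE, FALSE), dt = 0.1)
  for (r in list(liver, both, gut)) {
    expect_gte(r$auc_ratio, 1)
    expect_gte(r$cmax_ratio, 1 - 1e-9)
    expect_lte(r$fg_ratio, 1 / v$Fg + 1e-12)
  }
  expect_gte(both$auc_ratio, liver$auc_ratio)
  expect_gte(both$auc_ratio, gut$auc_ratio)
  # multiplicative decomposition for an oral victim (within 5%)
  expect_equal(both$auc_ratio, gut$auc_ratio * liver$auc_ratio,
               tolerance = 0.05)
})

test_that("exposure ratios shrink toward 1 as Ki grows", {
  v <- fast_victim(); p <- fast_perp()
  rr <- sapply(c(0.5, 2, 8, 32), function(ki)
    run_ddi_scenario(v, vreg, p, preg, inhibition_spec(ki, TRUE, TRUE),
                     dt = 0.1)$auc_ratio)
  expect_true(all(diff(rr) < 0))
  expect_gt(min(rr), 1)
})

test_that("liver-only ratio matches the static closed form for a near-flat inhibitor", {
  # slowly eliminated perpetrator: profile ~ constant at steady state
  v <- fast_victim()
  p <- fast_perp(CLint_h = 20)          # CLh ~ 3.8 L/h, long half-life
  r <- run_ddi_scenario(v, vreg, p, preg, inhibition_spec(1, FALSE, TRUE),
                        inlet = "systemic", dt = 0.1, max_cycles = 200)
  ss <- simulate_steady_state(p, preg, dt = 0.1, max_cycles = 200)
  iu <- p$fu_b * conc_to_uM(mean(ss$profile$conc), p$MW)
  fm <- v$fm_CYP3A4
  stat <- 1 / (fm / (1 + iu / 1) + (1 - fm))
  expect_equal(r$auc_ratio, stat, tolerance = 0.05)
})

test_that("staggering the victim dose mitigates the gut interaction", {
  v <- fast_victim(); p <- fast_perp()
  spec <- inhibition_spec(2, TRUE, FALSE)
  sc <- staggered_interval_scan(v, vreg, p, preg, spec,
                                offsets = c(0, 2, 4, 6), dt = 0.1)
  expect_equal(sc$offset, c(0, 2, 4, 6))
  expect_true(all(diff(sc$auc_ratio) <= 1e-9))   # non-increasing
  base <- run_ddi_scenario(v, vreg, p, preg, spec, offset = 0, dt = 0.1)
  expect_equal(sc$auc_ratio[1], base$auc_ratio)
  off <- staggered_interval_scan(v, vreg, p, preg,
                                 inhibition_spec(2, FALSE, FALSE),
                                 offsets = c(0, 3), dt = 0.1)
  expect_true(all(off$auc_ratio == 1))
  expect_error(staggered_interval_scan(v, vreg, p, preg, spec,
                                       offsets = 24), "cycle_length")
})

test_that("scenario runs are deterministic and validated", {
  v <- fast_victim(); p <- fast_perp()
  a <- run_ddi_scenario(v, vreg, p, preg, inhibition_spec(2), dt = 0.1)
  b <- run_ddi_scenario(v, vreg, p, preg, inhibition_spec(2), dt = 0.1)
  expect_identical(a$auc_ratio, b$auc_ratio)
  expect_identical(a$cmax_ratio, b$cmax_ratio)
  # fm is required for hepatic inhibition, with no silent default
  no_fm <- victim_disposition(test_params(), fm_CYP3A4 = 0.5)
  no_fm$fm_CYP3A4 <- NA_real_
  expect_error(run_ddi_scenario(no_fm, vreg, p, preg, inhibition_spec(2),
                                dt = 0.1), "fm_CYP3A4")
  # Fa*Fg consistency is an invariant
  expect_error(victim_disposition(test_params(), Fg = 0.9), "FaFg")
  # mismatched cycles are rejected
  preg12 <- regimen_schedule(100, 0, cycle_length = 12)
  expect_error(run_ddi_scenario(v, vreg, p, preg12, inhibition_spec(2),
                                dt = 0.1), "cycle length")
})

test_that("instant gut mode is at least as strong as the averaged mode at co-dosing", {
  v <- fast_victim(); p <- fast_perp()
  avg <- run_ddi_scenario(v, vreg, p, preg, inhibition_spec(2, TRUE, FALSE),
                          gut_model = "average", dt = 0.1)
  ins <- run_ddi_scenario(v, vreg, p, preg, inhibition_spec(2, TRUE, FALSE),
                          gut_model = "instant", dt = 0.1)
  expect_gte(ins$fg_ratio, avg$fg_ratio)
})
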