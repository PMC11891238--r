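#' MedDRA preferred terms packaged for the adverse-event analysis
#'
#' The 16 preferred terms (PTs) used by the packaged cyclosporine
#' adverse-event analysis, with their MedDRA numeric codes.  Only these
#' codes are packaged (MedDRA is a licensed terminology).
#'
#' @return Data frame with columns `name` and `pt_code`.
#' @export
meddra_pt_list <- function() {
  data.frame(
    name = c("drug-induced liver injury", "hyperlipidaemia", "hypertension",
             "renal failure", "vomiting", "nausea", "diarrhoea",
             "hyperglycaemia", "hyperkalaemia", "hyperuricaemia", "tremor",
             "gingival hypertrophy", "visual impairment", "hypertrichosis",
             "thrombotic microangiopathy", "rash"),
    pt_code = c(10072268L, 10062060L, 10020772L, 10038435L, 10047700L,
                10028813L, 10012735L, 10020635L, 10020646L, 10020903L,
                10044565L, 10018284L, 10047571L, 10020864L, 10043645L,
                10037844L),
    stringsAsFactors = FALSE)
}

#' Adverse-event definition
#'
#' @param name event label.
#' @param pt_code MedDRA PT numeric code; checked against the packaged
#'   list ([meddra_pt_list()]) with a warning when unknown.
#' @export
event_definition <- function(name, pt_code) {
  pt_code <- as.integer(pt_code)
  if (!pt_code %in% meddra_pt_list()$pt_code)
    warning("PT code ", pt_code, " is not in the packaged PT list")
  structure(list(name = name, pt_code = pt_code), class = "event_definition")
}

ROLE_CODES <- c("PS", "SS", "C", "I")

# Normalise a long report table (one row per case-drug-event) and check
# the schema.  Dates are ISO-8601 strings or Date.
check_reports <- function(reports) {
  need <- c("case_number", "version_date", "drug", "role_code", "pt_code")
  miss <- setdiff(need, names(reports))
  if (length(miss))
    stop("report table lacks columns: ", paste(miss, collapse = ", "))
  if (any(is.na(reports$case_number) | reports$case_number == ""))
    stop("empty case_number in report table")
  for (dcol in c("version_date", "start_date", "end_date", "event_date"))
    if (dcol %in% names(reports) && !inherits(reports[[dcol]], "Date"))
      reports[[dcol]] <- as.Date(reports[[dcol]])
  reports
}

#' Read a spontaneous-report CSV
#'
#' Documented long layout: one row per case-drug-event with columns
#' `case_number`, `version_date`, `drug`, `role_code`, `pt_code`,
#' `start_date`, `end_date`, `event_date` (ISO-8601 dates; `pt_code`
#' empty when a case-drug row carries no event).
#'
#' @param path CSV file.
#' @export
read_reports <- function(path) {
  check_reports(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c(case_number = "character")))
}

#' Deduplicate spontaneous reports by case number
#'
#' Keeps, for every case number, the rows of the most recent report
#' version (latest `version_date`); ties are broken by keeping the version
#' appearing last in the table (the largest version identifier when files
#' are appended chronologically).
#'
#' @param reports a long report table (see [read_reports()]).
#' @return The deduplicated table.
#' @export
deduplicate_reports <- function(reports) {
  reports <- check_reports(reports)
  if (nrow(reports) == 0) return(reports)
  latest <- stats::ave(as.integer(reports$version_date),
                       reports$case_number, FUN = max)
  reports[as.integer(reports$version_date) == latest, , drop = FALSE]
}

#' Apply the role-code and date-consistency filters
#'
#' Keeps cases in which every target drug carries a suspected role
#' (`PS` or `SS`); drops cases with a recorded administration start date
#' later than the event date (input error); drops, with a warning, cases
#' carrying a role code outside the closed set `PS/SS/C/I`.  Each
#' exclusion is tallied by reason and the tallies are additive to
#' `input cases - output cases`.
#'
#' @param reports a deduplicated long report table.
#' @param target_drugs drug names whose role must be PS/SS.
#' @return List: `reports` (filtered table), `exclusions` (named counts
#'   by reason: `role_code`, `date_error`, `unknown_role`),
#'   `n_in`, `n_out` (case counts).
#' @export
apply_report_filters <- function(reports, target_drugs) {
  reports <- check_reports(reports)
  cases <- unique(reports$case_number)
  n_in <- length(cases)
  bad_unknown <- unique(reports$case_number[
    !reports$role_code %in% ROLE_CODES])
  if (length(bad_unknown))
    warning(length(bad_unknown), " case(s) carry an unknown role code; excluded")
  tgt <- reports[reports$drug %in% target_drugs, , drop = FALSE]
  bad_role <- unique(tgt$case_number[!tgt$role_code %in% c("PS", "SS")])
  bad_role <- setdiff(bad_role, bad_unknown)
  bad_date <- character(0)
  if (all(c("start_date", "event_date") %in% names(reports))) {
    sel <- !is.na(reports$start_date) & !is.na(reports$event_date) &
      reports$start_date > reports$event_date
    bad_date <- setdiff(unique(reports$case_number[sel]),
                        c(bad_unknown, bad_role))
  }
  drop <- c(bad_unknown, bad_role, bad_date)
  out <- reports[!reports$case_number %in% drop, , drop = FALSE]
  list(reports = out,
       exclusions = c(unknown_role = length(bad_unknown),
                      role_code = length(bad_role),
                      date_error = length(bad_date)),
       n_in = n_in, n_out = length(unique(out$case_number)))
}

#' Build the exposure-by-event 2x2 contingency table
#'
#' Exposure group: cases reporting all `exposure` drugs.  Comparator
#' group: cases reporting all `comparator` drugs and none of the drugs in
#' `setdiff(exposure, comparator)`.  Cells are populated by presence of
#' the event PT code.
#'
#' @param reports a filtered long report table.
#' @param exposure,comparator character vectors of drug names; the
#'   comparator must be a strict subset of the exposure set (otherwise the
#'   two groups would overlap — a configuration error).
#' @param event an [event_definition()].
#' @return An object of class `contingency_table` with integer cells
#'   `a` (exposed, event), `b` (exposed, no event), `c` (comparator,
#'   event), `d` (comparator, no event) and the group sizes.
#' @export
contingency_table <- function(reports, exposure, comparator, event) {
  reports <- check_reports(reports)
  extra <- setdiff(exposure, comparator)
  if (length(extra) == 0)
    stop("exposure and comparator definitions overlap: ",
         "the comparator must lack at least one exposure drug")
  if (!all(comparator %in% exposure))
    warning("comparator drugs not contained in the exposure set; ",
            "groups may overlap")
  drugs_by_case <- split(reports$drug, reports$case_number)
  has_all <- function(set) vapply(drugs_by_case, function(d)
    all(set %in% d), TRUE)
  has_any <- function(set) vapply(drugs_by_case, function(d)
    any(set %in% d), TRUE)
  exp_cases <- names(drugs_by_case)[has_all(exposure)]
  cmp_cases <- names(drugs_by_case)[has_all(comparator) & !has_any(extra)]
  if (!event$pt_code %in% meddra_pt_list()$pt_code)
    warning("unknown PT code ", event$pt_code, ": event counts will be 0")
  ev_cases <- unique(reports$case_number[
    !is.na(reports$pt_code) & reports$pt_code == event$pt_code])
  a <- sum(exp_cases %in% ev_cases)
  cc <- sum(cmp_cases %in% ev_cases)
  structure(list(a = a, b = length(exp_cases) - a,
                 c = cc, d = length(cmp_cases) - cc,
                 n_exposed = length(exp_cases),
                 n_comparator = length(cmp_cases),
                 event = event$name, pt_code = event$pt_code),
            class = "contingency_table")
}

#' @rdname contingency_table
#' @param a,b,c,d non-negative integer cell counts (exposed with/without
#'   event, comparator with/without event), for building a table directly.
#' @export
contingency_counts <- function(a, b, c, d, event = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, n_exposed = a + b,
                 n_comparator = c + d,
                 event = if (is.character(event)) event else event$name,
                 pt_code = NA_integer_),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", if (!is.na(x$event)) x$event else "", "\n")
  print(matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
               dimnames = list(c("exposed", "comparator"),
                               c("event", "no event"))))
  invisible(x)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' \eqn{ROR = ad/bc} with the Woolf (log-normal) confidence interval
#' \eqn{\exp(\ln ROR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d})}.  The default
#' p-value is the Wald test on the log odds ratio, matching the univariate
#' logistic-regression framing (the point estimate and p are numerically
#' identical to `exp(coef)` and the Wald p of a logistic fit on the same
#' 2x2); chi-square and Fisher tests are available as labelled
#' alternatives.  A signal is declared when the lower CI bound exceeds 1.
#'
#' The ROR is not assessable when the exposure group is empty or when any
#' cell is zero (undefined estimate or infinite-variance CI); the
#' Haldane-Anscombe +0.5 correction can be requested explicitly instead
#' (no silent correction by default).
#'
#' @param table a `contingency_table`.
#' @param correction `"none"` (default) or `"haldane"` (+0.5 to every
#'   cell).
#' @param p_method `"wald"` (default), `"chisq"` or `"fisher"`.
#' @return An object of class `ror_result`: `ror`, `ci_low`, `ci_high`,
#'   `p_value`, `assessable`, `significant`, plus the cells used.
#' @export
reporting_odds_ratio <- function(table, correction = c("none", "haldane"),
                                 p_method = c("wald", "chisq", "fisher")) {
  correction <- match.arg(correction)
  p_method <- match.arg(p_method)
  cells <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  if (any(cells < 0)) stop("negative cell counts")
  if (correction == "haldane") cells <- cells + 0.5
  empty_exposure <- (table$a + table$b) == 0
  assessable <- !empty_exposure && all(cells > 0)
  if (!assessable) {
    return(structure(list(ror = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          assessable = FALSE, significant = FALSE,
                          cells = cells, event = table$event,
                          p_method = p_method),
                     class = "ror_result"))
  }
  ror <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(ror) + c(-1, 1) * 1.96 * se)
  p <- switch(p_method,
    wald = 2 * stats::pnorm(-abs(log(ror) / se)),
    chisq = stats::chisq.test(matrix(c(table$a, table$b, table$c, table$d),
                                     2, 2, byrow = TRUE),
                              correct = FALSE)$p.value,
    fisher = stats::fisher.test(matrix(c(table$a, table$b, table$c,
                                         table$d), 2, 2,
                                       byrow = TRUE))$p.value)
  structure(list(ror = unname(ror), ci_low = ci[1], ci_high = ci[2],
                 p_value = unname(p), assessable = TRUE,
                 significant = ci[1] > 1, cells = cells,
                 event = table$event, p_method = p_method),
            class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  if (!x$assessable) {
    cat("<ror_result> not assessable (insufficient reports)\n")
  } else {
    cat(sprintf("<ror_result> ROR %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
                x$ror, x$ci_low, x$ci_high, x$p_value,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Full disproportionality pipeline on a report table
#'
#' Fixed filter order (deduplicate, role filter, date filter), then a
#' 2x2 table and ROR per event.  Deterministic: identical input gives
#' identical output.
#'
#' @inheritParams contingency_table
#' @param events list of [event_definition()]s; default the packaged PT
#'   list.
#' @param ... passed to [reporting_odds_ratio()].
#' @return List: `results` (data frame, one row per event), `exclusions`,
#'   `n_exposed`, `n_comparator`.
#' @export
ror_pipeline <- function(reports, exposure, comparator, events = NULL,
                         ...) {
  if (is.null(events)) {
    pts <- meddra_pt_list()
    events <- lapply(seq_len(nrow(pts)), function(i)
      event_definition(pts$name[i], pts$pt_code[i]))
  }
  dd <- deduplicate_reports(reports)
  fl <- apply_report_filters(dd, target_drugs = union(exposure, comparator))
  rows <- lapply(events, function(ev) {
    tab <- contingency_table(fl$reports, exposure, comparator, ev)
    r <- reporting_odds_ratio(tab, ...)
    data.frame(event = ev$name, pt_code = ev$pt_code,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, assessable = r$assessable,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  first <- contingency_table(fl$reports, exposure, comparator,
                             suppressWarnings(
                               event_definition("any", events[[1]]$pt_code)))
  list(results = do.call(rbind, rows), exclusions = fl$exclusions,
       n_exposed = first$n_exposed, n_comparator = first$n_comparator)
}
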