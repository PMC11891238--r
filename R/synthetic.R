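#' Noise specification for synthetic PK observations
#'
#' @param proportional_cv fractional (proportional) noise CV.
#' @param additive_sd additive noise SD (ng/mL).
#' @param sample_times sampling times (h).
#' @param seed RNG seed.
#' @export
pk_noise_spec <- function(proportional_cv = 0.1, additive_sd = 0,
                          sample_times = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 10,
                                           12, 18, 24),
                          seed = 1) {
  if (proportional_cv < 0 || additive_sd < 0)
    stop("noise magnitudes must be >= 0")
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd,
                 sample_times = sample_times, seed = as.integer(seed)),
            class = "pk_noise_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate noisy concentration-time observations from a known model
#'
#' Observations are the exact closed-form simulation of `truth` under
#' `regimen`, perturbed as
#' `obs = sim * (1 + cv * e1) + sd * e2` with standard-normal `e1, e2`,
#' floored at zero.  Seeded and reproducible; the generating parameters
#' ride along for parameter-recovery tests.
#'
#' @param truth a [compartmental_params()] generating the data.
#' @param regimen a [pk_regimen()].
#' @param noise a [pk_noise_spec()].
#' @param lloq,uloq assay limits passed to [pk_observations()].
#' @return A [pk_observations()] with `truth` attached.
#' @export
generate_pk_observations <- function(truth, regimen, noise,
                                     lloq = NA, uloq = NA) {
  sim <- analytic_profile(truth, regimen, noise$sample_times)$conc
  obs <- with_seed(noise$seed, {
    e1 <- stats::rnorm(length(sim)); e2 <- stats::rnorm(length(sim))
    pmax(sim * (1 + noise$proportional_cv * e1) +
           noise$additive_sd * e2, 0)
  })
  pk_observations(noise$sample_times, obs, regimen, lloq = lloq,
                  uloq = uloq, truth = truth)
}

#' Specification of a synthetic spontaneous-report cohort
#'
#' Defaults mirror the scale of the packaged cyclosporine analysis: 9,144
#' comparator (victim-only) cases and 174 exposed (victim + perpetrator)
#' cases, with a share of duplicated case versions and of date input
#' errors planted for the cleaning steps to find.
#'
#' @param n_comparator,n_exposed case counts (after cleaning, for cases
#'   free of planted errors).
#' @param event_rates named numeric vector of baseline per-event
#'   probabilities (names are PT codes or event names from
#'   [meddra_pt_list()]).
#' @param planted_or per-event odds ratio in the exposed group (recycled).
#' @param dup_fraction share of cases that receive an extra, older report
#'   version (so deduplication removes it).
#' @param date_error_fraction share of cases given a start date after the
#'   event date (so the date filter removes them).
#' @param seed RNG seed.
#' @export
report_cohort_spec <- function(n_comparator = 9144, n_exposed = 174,
                               event_rates = c("10072268" = 0.02,
                                               "10043645" = 0.03,
                                               "10044565" = 0.03),
                               planted_or = 1,
                               dup_fraction = 0.10,
                               date_error_fraction = 0.02,
                               seed = 1) {
  if (any(event_rates < 0 | event_rates > 1))
    stop("event rates must lie in [0, 1]")
  if (any(planted_or <= 0)) stop("'planted_or' must be > 0")
  if (n_comparator < 0 || n_exposed < 0) stop("counts must be >= 0")
  if (dup_fraction < 0 || dup_fraction > 1 ||
      date_error_fraction < 0 || date_error_fraction > 1)
    stop("fractions must lie in [0, 1]")
  structure(list(n_comparator = n_comparator, n_exposed = n_exposed,
                 event_rates = event_rates,
                 planted_or = rep(planted_or,
                                  length.out = length(event_rates)),
                 dup_fraction = dup_fraction,
                 date_error_fraction = date_error_fraction,
                 seed = as.integer(seed)),
            class = "report_cohort_spec")
}

#' Generate a synthetic spontaneous-report cohort with a planted signal
#'
#' Builds a long report table in the documented CSV layout.  Comparator
#' cases report the victim drug only (role PS); exposed cases add the
#' perpetrator drug (role SS).  Events are drawn per case with the
#' baseline probability in the comparator group and with odds multiplied
#' by `planted_or` in the exposed group.  A `dup_fraction` share of cases
#' gets an additional older version; a `date_error_fraction` share gets a
#' start date after the event date.  Report dates are drawn uniformly in
#' 2004-2024 (cosmetic, mirroring a 20-year extraction window).
#'
#' @param spec a [report_cohort_spec()].
#' @param victim,perpetrator drug names used in the table.
#' @return The report table (data frame) with attribute `truth`: a data
#'   frame of the planted per-event cell counts (`a`, `b`, `c`, `d`)
#'   among cases that survive cleaning, for exact oracle checks.
#' @export
generate_report_cohort <- function(spec, victim = "cyclosporine",
                                   perpetrator = "voriconazole") {
  stopifnot(inherits(spec, "report_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_comparator + spec$n_exposed
    exposed <- rep(c(FALSE, TRUE), c(spec$n_comparator, spec$n_exposed))
    case <- sprintf("C%07d", seq_len(n))
    vdate <- as.Date("2004-01-01") +
      sample.int(7395, n, replace = TRUE) - 1
    date_err <- stats::runif(n) < spec$date_error_fraction
    start <- vdate - sample.int(365, n, replace = TRUE)
    event_date <- start + sample.int(180, n, replace = TRUE)
    event_date[date_err] <- start[date_err] - sample.int(30, sum(date_err),
                                                         replace = TRUE)
    # per-event outcomes
    codes <- names(spec$event_rates)
    ev_mat <- matrix(FALSE, n, length(codes),
                     dimnames = list(NULL, codes))
    for (j in seq_along(codes)) {
      p0 <- spec$event_rates[j]
      odds <- p0 / (1 - p0) * ifelse(exposed, spec$planted_or[j], 1)
      ev_mat[, j] <- stats::runif(n) < odds / (1 + odds)
    }
    pt_by_case <- lapply(seq_len(n), function(i) {
      v <- codes[ev_mat[i, ]]
      if (length(v)) as.integer(v) else NA_integer_
    })
    n_ev <- lengths(pt_by_case)
    idx <- rep(seq_len(n), n_ev)
    pt_all <- unlist(pt_by_case)
    block <- function(sel, drg, role) {
      ii <- idx[sel]
      data.frame(
        case_number = case[ii], version_date = vdate[ii],
        drug = rep(drg, length(ii)), role_code = rep(role, length(ii)),
        pt_code = pt_all[sel], start_date = start[ii],
        end_date = event_date[ii] + 30, event_date = event_date[ii],
        stringsAsFactors = FALSE)
    }
    tab <- rbind(block(rep(TRUE, length(idx)), victim, "PS"),
                 block(exposed[idx], perpetrator, "SS"))
    # planted duplicates: an older version of the same case
    dup_idx <- which(stats::runif(n) < spec$dup_fraction)
    if (length(dup_idx)) {
      dups <- tab[tab$case_number %in% case[dup_idx], , drop = FALSE]
      dups$version_date <- dups$version_date - 200
      tab <- rbind(tab, dups)
    }
    tab <- tab[order(tab$case_number, tab$version_date), ]
    rownames(tab) <- NULL
    clean <- !date_err
    truth <- do.call(rbind, lapply(seq_along(codes), function(j) {
      a <- sum(ev_mat[clean & exposed, j])
      cc <- sum(ev_mat[clean & !exposed, j])
      data.frame(pt_code = as.integer(codes[j]),
                 planted_or = spec$planted_or[j],
                 a = a, b = sum(clean & exposed) - a,
                 c = cc, d = sum(clean & !exposed) - cc)
    }))
    attr(tab, "truth") <- truth
    attr(tab, "n_duplicated") <- length(dup_idx)
    attr(tab, "n_date_error") <- sum(date_err)
    tab
  })
}

#' Clinical case timeline fixture (synthetic reconstruction)
#'
#' Returns the packaged demonstration timeline of the motivating clinical
#' course: blood cyclosporine levels, C/D ratios and renal function across
#' the antifungal periods (liposomal amphotericin B, voriconazole,
#' isavuconazole, micafungin).  Values are the published point readings;
#' rows where interim dose changes are implied but not recorded carry
#' `dose_known = FALSE` and a provenance note.  This is a demonstration
#' fixture, not a test oracle.
#'
#' @return Data frame (`date`, `period`, `conc_ng_per_mL`,
#'   `daily_dose_mg`, `dose_known`, `weight_kg`, `scr_mg_per_dL`, `sex`,
#'   `age`, `note`).
#' @export
case_timeline_fixture <- function() {
  path <- system.file("extdata", "case_timeline_synthetic.csv",
                      package = "pbpkddi", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  out
}

#' Reconstructed supplementary event counts (synthetic)
#'
#' The published analysis reports, for the victim + voriconazole stratum
#' versus the victim-only stratum (174 vs 9,144 cases), three significant
#' reporting odds ratios with their confidence intervals, but not the
#' underlying event counts.  This fixture holds the integer 2x2 cell
#' counts reconstructed by exhaustive search as the tables closest to the
#' printed ROR and CI at those group sizes (exact to two decimals for
#' tremor and the liver-injury CI; within 0.02 elsewhere — no integer
#' table reproduces every printed figure exactly).  Labelled synthetic;
#' used to exercise the disproportionality pipeline end to end.
#'
#' @return Data frame with columns `event`, `pt_code`, `a`, `b`, `c`, `d`
#'   and the printed reference values.
#' @export
sm1_reconstructed <- function() {
  path <- system.file("extdata", "sm1_counts_reconstructed.csv",
                      package = "pbpkddi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expand 2x2 counts into a synthetic report table
#'
#' Builds a long report table whose pipeline output reproduces the given
#' per-event cell counts exactly (shared exposure/comparator groups sized
#' by the first row's margins), for end-to-end pipeline checks against
#' known tables.
#'
#' @param counts data frame like [sm1_reconstructed()] (columns
#'   `pt_code`, `a`, `b`, `c`, `d`; margins `a+b` and `c+d` must agree
#'   across rows).
#' @param victim,perpetrator drug names.
#' @return A long report table in the documented layout.
#' @export
reports_from_counts <- function(counts, victim = "cyclosporine",
                                perpetrator = "voriconazole") {
  n_exp <- unique(counts$a + counts$b)
  n_cmp <- unique(counts$c + counts$d)
  if (length(n_exp) != 1 || length(n_cmp) != 1)
    stop("group margins must agree across events")
  n <- n_exp + n_cmp
  exposed <- rep(c(TRUE, FALSE), c(n_exp, n_cmp))
  case <- sprintf("S%07d", seq_len(n))
  base <- as.Date("2015-06-01")
  # the first a (resp. c) cases of each group carry each event
  pt_by_case <- lapply(seq_len(n), function(i) {
    k <- if (exposed[i]) i else i - n_exp
    lim <- if (exposed[i]) counts$a else counts$c
    v <- counts$pt_code[k <= lim]
    if (length(v)) as.integer(v) else NA_integer_
  })
  idx <- rep(seq_len(n), lengths(pt_by_case))
  pt_all <- unlist(pt_by_case)
  block <- function(sel, drg, role) {
    ii <- idx[sel]
    data.frame(
      case_number = case[ii], version_date = base,
      drug = rep(drg, length(ii)), role_code = rep(role, length(ii)),
      pt_code = pt_all[sel], start_date = base - 100, end_date = base - 10,
      event_date = base - 50, stringsAsFactors = FALSE)
  }
  out <- rbind(block(rep(TRUE, length(idx)), victim, "PS"),
               block(exposed[idx], perpetrator, "SS"))
  out[order(out$case_number), , drop = FALSE]
}
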