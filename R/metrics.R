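#' Exposure metrics from a concentration-time profile
#'
#' Computes AUC (trapezoid on the grid), Cmax (grid maximum with local
#' quadratic refinement), concentrations at named post-dose times
#' (interpolated) and the trough (concentration at the window end).
#'
#' @param profile a `concentration_profile`.
#' @param window two-element numeric, the `[t0, t1]` evaluation window (h);
#'   must lie within the profile support.
#' @param post_dose_times times after `dose_time` at which concentrations
#'   are reported, e.g. `2` for C2.
#' @param dose_time reference dose time for `post_dose_times`; defaults to
#'   the window start.
#' @return An object of class `exposure_metrics` with fields `auc`
#'   (ng·h/mL; use [auc_convert()] for other reporting units), `cmax`,
#'   `tmax`, `c_at` (named vector) and `ctrough` (ng/mL).
#' @export
exposure_metrics <- function(profile, window,
                             post_dose_times = numeric(0),
                             dose_time = window[1]) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("'window' must be an increasing pair [t0, t1]")
  if (window[1] < min(profile$time) - 1e-9 ||
      window[2] > max(profile$time) + 1e-9)
    stop("window outside profile support")
  sel <- profile$time >= window[1] - 1e-12 & profile$time <= window[2] + 1e-12
  tt <- profile$time[sel]; cc <- profile$conc[sel]
  # interpolated window endpoints
  if (length(tt) == 0 || tt[1] > window[1] + 1e-12) {
    tt <- c(window[1], tt); cc <- c(interp_conc(profile, window[1]), cc)
  }
  if (tt[length(tt)] < window[2] - 1e-12) {
    tt <- c(tt, window[2]); cc <- c(cc, interp_conc(profile, window[2]))
  }
  auc <- trapz_auc(tt, cc)
  im <- which.max(cc)
  cmax <- cc[im]; tmax <- tt[im]
  if (im > 1 && im < length(cc)) {
    # quadratic vertex through the three points around the grid maximum
    x <- tt[(im - 1):(im + 1)]; y <- cc[(im - 1):(im + 1)]
    d21 <- (y[2] - y[1]) / (x[2] - x[1]); d32 <- (y[3] - y[2]) / (x[3] - x[2])
    curv <- (d32 - d21) / (x[3] - x[1])
    if (is.finite(curv) && curv < 0) {
      tv <- (x[1] + x[2]) / 2 - d21 / (2 * curv)
      if (tv > x[1] && tv < x[3]) {
        cv <- y[2] + d21 * (tv - x[2]) + curv * (tv - x[1]) * (tv - x[2])
        if (cv >= cmax) { cmax <- cv; tmax <- tv }
      }
    }
  }
  c_at <- if (length(post_dose_times))
    stats::setNames(interp_conc(profile, dose_time + post_dose_times),
                    paste0("C", post_dose_times)) else numeric(0)
  structure(list(auc = auc, cmax = cmax, tmax = tmax, c_at = c_at,
                 ctrough = interp_conc(profile, window[2]),
                 window = window),
            class = "exposure_metrics")
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf("<exposure_metrics> window %g-%g h\n", x$window[1], x$window[2]))
  cat(sprintf("  AUC %.5g ng.h/mL | Cmax %.5g ng/mL (t %.3g h) | trough %.5g\n",
              x$auc, x$cmax, x$tmax, x$ctrough))
  if (length(x$c_at))
    cat("  ", paste(names(x$c_at), signif(x$c_at, 5), collapse = " | "), "\n")
  invisible(x)
}

trapz_auc <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Simulate a regimen to steady state
#'
#' Runs the ODE model cycle by cycle, optionally after a loading phase,
#' until the per-cycle AUC changes by less than `ss_tol` (relative) between
#' successive maintenance cycles, then returns the final cycle.
#'
#' @inheritParams simulate_profile
#' @param loading optional [pk_regimen()] administered before the
#'   maintenance regimen (e.g. a two-day loading schedule); its `n_cycles`
#'   are simulated first.
#' @param shift constant shift of maintenance dose times within the cycle
#'   (h, `0 <= shift < cycle_length`), used for staggered dosing.
#' @param max_cycles maintenance-cycle budget before giving up.
#' @param ss_tol relative per-cycle AUC change declaring steady state.
#' @param dt output grid step (h).
#' @param clint_fun,fg_fun optional time-varying intrinsic clearance
#'   function and per-dose gut availability function `f(dose_time) -> Fg`,
#'   used by the interaction engine.  `clint_fun` takes absolute time.
#' @return List with `profile` (final maintenance cycle, rebased to
#'   `[0, cycle_length]`), `n_cycles`, `converged`, `auc_by_cycle`, and
#'   `states0` (compartment amounts at the final cycle start).
#' @export
simulate_steady_state <- function(params, regimen, loading = NULL,
                                  shift = 0, max_cycles = 80,
                                  ss_tol = 1e-3, dt = 0.05,
                                  clint_fun = NULL, fg_fun = NULL) {
  tau <- regimen$cycle_length
  if (shift < 0 || shift >= tau) stop("'shift' must lie in [0, cycle_length)")
  y <- c(Alum = 0, A1 = 0, A2 = 0)
  t0 <- 0
  dose_fg <- function(d) {
    if (is.null(fg_fun)) rep(NA_real_, nrow(d))
    else vapply(seq_len(nrow(d)), function(i)
      if (d$route[i] == "oral") fg_fun(d$time[i]) else NA_real_, 0)
  }
  run_span <- function(doses, from, to) {
    grid <- seq(from, to, by = dt)
    if (abs(grid[length(grid)] - to) > 1e-9) grid <- c(grid, to)
    ode_core(params, doses, grid, fg = dose_fg(doses),
             clint_fun = clint_fun, y0 = y)
  }
  if (!is.null(loading)) {
    ld <- expand_regimen(loading)
    sim <- run_span(ld, t0, regimen_duration(loading))
    y <- sim$states[nrow(sim$states), ]
    t0 <- regimen_duration(loading)
  }
  ev <- regimen$events
  aucs <- numeric(0)
  converged <- FALSE
  last <- NULL
  for (cy in seq_len(max_cycles)) {
    d <- ev
    d$time <- d$time + shift + t0
    sim <- run_span(d, t0, t0 + tau)
    y <- sim$states[nrow(sim$states), ]
    a <- trapz_auc(sim$times, sim$conc)
    aucs <- c(aucs, a)
    last <- sim
    if (cy > 1 && a > 0 &&
        abs(a / aucs[cy - 1] - 1) < ss_tol) { converged <- TRUE; break }
    t0 <- t0 + tau
  }
  if (!converged)
    warning("steady state not reached within ", max_cycles, " cycles")
  prof <- concentration_profile(last$times - last$times[1], last$conc)
  attr(prof, "states") <- last$states
  list(profile = prof, n_cycles = length(aucs), converged = converged,
       auc_by_cycle = aucs, states0 = last$states[1, ],
       cycle_start = last$times[1])
}
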