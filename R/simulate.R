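#' @importFrom deSolve lsoda
#' @importFrom stats approxfun approx setNames
#' @importFrom utils head tail
NULL

# Disposition exponents (lambda1 > lambda2 > 0) of the two-compartment
# system with elimination rate k10 = (CLh + CLr)/V1.
disposition_rates <- function(params, CLint_h = params$CLint_h) {
  k10 <- (hepatic_clearance(params, CLint_h) + params$CLr) / params$V1
  a <- k10 + params$k12 + params$k21
  b <- k10 * params$k21
  disc <- sqrt(max(a^2 - 4 * b, 0))
  c(lambda1 = (a + disc) / 2, lambda2 = (a - disc) / 2, k10 = k10)
}

#' Closed-form concentration after a single dose
#'
#' Tri-exponential (oral) or bi-exponential (IV bolus) solution of the
#' two-compartment model, used as the independent oracle for the ODE
#' back-end.  When the absorption rate coincides with a disposition
#' exponent the confluent (repeated-root) limiting form is evaluated
#' instead of the generic formula.
#'
#' @param params a [compartmental_params()] object.
#' @param dose a [dose_event()] (single row; oral or IV bolus).
#' @param t times (h) at which to evaluate; concentrations before the dose
#'   time are zero.
#' @return Central-compartment concentration (ng/mL) at `t`.
#' @export
analytic_single_dose <- function(params, dose, t) {
  if (nrow(dose) != 1L) stop("'dose' must be a single dose event")
  if (dose$route == "intravenous" && dose$infusion_duration > 0)
    stop("analytic solution implemented for bolus and oral doses only")
  lam <- disposition_rates(params)
  l1 <- lam[["lambda1"]]; l2 <- lam[["lambda2"]]
  k21 <- params$k21
  tt <- t - dose$time
  out <- numeric(length(t))
  live <- tt >= 0
  if (!any(live)) return(out)
  s <- tt[live]
  V1_mL <- params$V1 * 1000
  if (dose$route == "intravenous") {
    A <- (l1 - k21) / (l1 - l2)
    B <- (k21 - l2) / (l1 - l2)
    out[live] <- dose$amount * 1e6 / V1_mL *
      (A * exp(-l1 * s) + B * exp(-l2 * s))
    return(out)
  }
  ka <- params$ka
  FF <- oral_bioavailability(params)
  sc <- FF * dose$amount * 1e6 * ka / V1_mL
  eps <- 1e-9 * ka
  if (abs(ka - l1) > eps && abs(ka - l2) > eps) {
    A <- (k21 - l1) / ((ka - l1) * (l2 - l1))
    B <- (k21 - l2) / ((ka - l2) * (l1 - l2))
    Ck <- (k21 - ka) / ((l1 - ka) * (l2 - ka))
    out[live] <- sc * (A * exp(-l1 * s) + B * exp(-l2 * s) +
                         Ck * exp(-ka * s))
  } else {
    # repeated root ka == lr; lo is the other exponent
    if (abs(ka - l1) <= eps) { lr <- l1; lo <- l2 } else { lr <- l2; lo <- l1 }
    out[live] <- sc * (exp(-lr * s) * ((k21 - lr) * s / (lo - lr) +
                                         (lo - k21) / (lo - lr)^2) +
                         exp(-lo * s) * (k21 - lo) / (lr - lo)^2)
  }
  out
}

#' Closed-form multiple-dose profile by superposition
#'
#' Sums [analytic_single_dose()] over every administration of a regimen.
#' Valid because the model is linear; used as oracle and as the fast
#' prediction function for model fitting.
#'
#' @inheritParams simulate_profile
#' @param shift constant shift applied to all dose times (h).
#' @return A `concentration_profile`.
#' @export
analytic_profile <- function(params, regimen, grid, shift = 0) {
  doses <- expand_regimen(regimen, shift)
  conc <- numeric(length(grid))
  for (i in seq_len(nrow(doses)))
    conc <- conc + analytic_single_dose(params, doses[i, , drop = FALSE], grid)
  concentration_profile(grid, conc)
}

# Core ODE integrator over an expanded dose table.
# doses: data.frame(amount mg, time h, route, infusion_duration)
# fg:    per-dose gut availability override (Fg, not FaFg); NA = baseline
# clint_fun: function(t) -> effective hepatic intrinsic clearance (L/h)
# Returns list(times, states [Alum, A1, A2 in ng], conc ng/mL)
ode_core <- function(params, doses, times, fg = NULL, clint_fun = NULL,
                     y0 = c(Alum = 0, A1 = 0, A2 = 0),
                     rtol = 1e-8, atol_conc = 1e-6) {
  stopifnot(!is.unsorted(times))
  V1_mL <- params$V1 * 1000
  Fg_base <- params$FaFg / params$Fa
  if (is.null(fg)) fg <- rep(NA_real_, nrow(doses))
  fg[is.na(fg)] <- Fg_base

  ev <- NULL
  infus <- NULL
  if (nrow(doses) > 0) {
    for (i in seq_len(nrow(doses))) {
      d <- doses[i, ]
      if (d$route == "oral") {
        ev <- rbind(ev, data.frame(var = "Alum", time = d$time,
                                   value = d$amount * 1e6 * params$Fa * fg[i],
                                   method = "add"))
      } else if (d$infusion_duration > 0) {
        infus <- rbind(infus, data.frame(start = d$time,
                                         end = d$time + d$infusion_duration,
                                         rate = d$amount * 1e6 / d$infusion_duration))
      } else {
        ev <- rbind(ev, data.frame(var = "A1", time = d$time,
                                   value = d$amount * 1e6, method = "add"))
      }
    }
  }
  # zero-value events at infusion boundaries force integrator restarts so
  # the rate discontinuity is never stepped across
  if (!is.null(infus)) {
    ev <- rbind(ev, data.frame(var = "A1",
                               time = c(infus$start, infus$end),
                               value = 0, method = "add"))
    ev <- ev[order(ev$time), , drop = FALSE]
  }
  # events exactly at the first output time are applied to the state directly
  if (!is.null(ev)) {
    at0 <- ev$time <= times[1] + 1e-12
    for (j in which(at0)) y0[ev$var[j]] <- y0[ev$var[j]] + ev$value[j]
    ev <- ev[!at0, , drop = FALSE]
    if (nrow(ev) == 0) ev <- NULL
  }
  times_run <- sort(unique(c(times, ev$time, infus$start, infus$end)))

  CLh0 <- hepatic_clearance(params)
  deriv <- function(t, y, parms) {
    CLh <- if (is.null(clint_fun)) CLh0 else
      hepatic_clearance(params, clint_fun(t))
    ER <- CLh / params$Qh
    inf_rate <- if (is.null(infus)) 0 else
      sum(infus$rate[infus$start <= t & t < infus$end])
    absorbed <- params$ka * y[1]
    dAl <- -absorbed
    dA1 <- absorbed * (1 - ER) + params$k21 * y[3] - params$k12 * y[2] -
      (CLh + params$CLr) / params$V1 * y[2] + inf_rate
    dA2 <- params$k12 * y[2] - params$k21 * y[3]
    list(c(dAl, dA1, dA2))
  }
  out <- deSolve::lsoda(y = y0, times = times_run, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol_conc * V1_mL,
                        events = if (is.null(ev)) NULL else list(data = ev),
                        maxsteps = 50000)
  keep <- match(round(times, 10), round(out[, 1], 10))
  states <- out[keep, -1, drop = FALSE]
  colnames(states) <- c("Alum", "A1", "A2")
  list(times = times, states = states, conc = pmax(states[, "A1"] / V1_mL, 0))
}

#' Simulate a concentration-time profile
#'
#' Integrates the two-compartment model with first-order oral absorption
#' (and IV bolus/infusion input) over a regimen.  Dose events are handled
#' by integrator restarts, not smearing.  The default back-end is the stiff
#' ODE solver (`deSolve::lsoda`, rtol 1e-8, atol 1e-6 ng/mL); the
#' closed-form superposition back-end gives identical results for constant
#' parameters and is used as its oracle.
#'
#' @param params a [compartmental_params()] object.
#' @param regimen a [pk_regimen()].
#' @param grid output time grid (h); must cover all dose events.  Defaults
#'   to a 0.05 h grid over the regimen duration.
#' @param method `"ode"` or `"analytic"`.
#' @param fg_per_dose optional per-administration gut availability override
#'   (vector along [expand_regimen()] rows; `NA` = baseline), used by the
#'   interaction engine.
#' @param clint_fun optional function of time returning the effective
#'   hepatic intrinsic clearance (L/h), used by the interaction engine.
#' @return A `concentration_profile`: data frame (`time`, `conc` in ng/mL)
#'   with the compartment amounts (ng) attached as attribute `states`.
#' @export
simulate_profile <- function(params, regimen, grid = NULL,
                             method = c("ode", "analytic"),
                             fg_per_dose = NULL, clint_fun = NULL) {
  method <- match.arg(method)
  if (!inherits(params, "compartmental_params"))
    stop("'params' must be a compartmental_params object")
  if (is.null(grid))
    grid <- seq(0, regimen_duration(regimen), by = 0.05)
  doses <- expand_regimen(regimen)
  if (nrow(doses) > 0 && max(doses$time) > max(grid) + 1e-9)
    stop("time grid does not cover all dose events")
  if (method == "analytic") {
    if (!is.null(fg_per_dose) || !is.null(clint_fun))
      stop("per-dose Fg / time-varying CLint require method = 'ode'")
    return(analytic_profile(params, regimen, grid))
  }
  sim <- ode_core(params, doses, grid, fg = fg_per_dose,
                  clint_fun = clint_fun)
  prof <- concentration_profile(sim$times, sim$conc)
  attr(prof, "states") <- sim$states
  attr(prof, "doses") <- doses
  prof
}

#' Concentration-time profile container
#'
#' @param times strictly increasing time grid (h).
#' @param conc concentrations (ng/mL), non-negative; values within solver
#'   noise below zero are clipped.
#' @export
concentration_profile <- function(times, conc) {
  if (is.unsorted(times, strictly = TRUE))
    stop("profile times must be strictly increasing")
  if (any(conc < -1e-6)) stop("negative concentrations in profile")
  structure(data.frame(time = times, conc = pmax(conc, 0)),
            class = c("concentration_profile", "data.frame"))
}

#' Interpolate a profile at arbitrary times
#' @param profile a `concentration_profile`.
#' @param t times (h) within the profile support.
#' @export
interp_conc <- function(profile, t) {
  if (any(t < min(profile$time) - 1e-9 | t > max(profile$time) + 1e-9))
    stop("interpolation time outside profile support")
  stats::approx(profile$time, profile$conc, xout = t, rule = 2)$y
}

#' Export a profile as CSV (`time_h`, `conc_ng_per_mL`)
#' @param profile a `concentration_profile`.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(time_h = profile$time,
                              conc_ng_per_mL = profile$conc),
                   path, row.names = FALSE)
  invisible(path)
}
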