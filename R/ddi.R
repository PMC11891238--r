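#' Competitive inhibition of intrinsic clearance
#'
#' \deqn{CL_{int}' = CL_{int} / (1 + I_u/K_i)}
#'
#' @param CLint intrinsic clearance (L/h).
#' @param I_u unbound inhibitor concentration at the enzyme (uM); may be a
#'   vector.
#' @param Ki competitive inhibition constant (uM).
#' @return Inhibited intrinsic clearance (L/h), monotone decreasing in `I_u`.
#' @export
inhibited_intrinsic_clearance <- function(CLint, I_u, Ki) {
  if (any(CLint < 0) || any(I_u < 0) || Ki <= 0)
    stop("CLint and I_u must be >= 0 and Ki > 0")
  CLint / (1 + I_u / Ki)
}

#' Gut-wall availability under inhibition
#'
#' Hybrid availability model: with baseline availability `Fg_base` and an
#' inhibited/baseline gut intrinsic clearance ratio `r`,
#' \deqn{F_g' = 1 / (1 + (1/F_g - 1) r).}
#' `r = 1` returns the baseline, `r = 0` (complete inhibition) returns 1.
#' Algebraically identical to the flow form `Fg = Q/(Q + CLg)` with the gut
#' clearance scaled by `r`.
#'
#' @param Fg_base baseline gut availability, in (0, 1].
#' @param CLint_g_ratio inhibited/baseline gut intrinsic clearance ratio,
#'   in \[0, 1\].
#' @return Inhibited availability `Fg'` in `[Fg_base, 1]`.
#' @export
gut_availability <- function(Fg_base, CLint_g_ratio) {
  if (any(Fg_base <= 0) || any(Fg_base > 1))
    stop("'Fg_base' must lie in (0, 1]")
  if (any(CLint_g_ratio < 0) || any(CLint_g_ratio > 1))
    stop("'CLint_g_ratio' must lie in [0, 1]")
  1 / (1 + (1 / Fg_base - 1) * CLint_g_ratio)
}

#' Static enterocyte inhibitor concentration estimate
#'
#' Quasi-steady enterocyte exposure during absorption: absorption rate at
#' its peak divided by the enterocyte (villous) blood flow,
#' \deqn{I_g = D k_a F_a / Q_{ent}} converted to micromolar.  The dynamic
#' generalisation used by the scenario engine decays this with the
#' perpetrator absorption rate (see [gut_inhibitor_profile()]).
#'
#' @param dose dose (mg).
#' @param ka absorption rate constant (1/h).
#' @param Fa fraction absorbed.
#' @param MW molecular weight (g/mol).
#' @param Qent enterocyte blood flow (L/h); packaged constant 18 L/h.
#' @return Concentration in uM; linear in dose.
#' @export
gut_inhibitor_concentration <- function(dose, ka, Fa, MW, Qent = 18) {
  if (MW <= 0) stop("'MW' must be > 0")
  if (dose < 0 || ka <= 0 || Fa <= 0 || Qent <= 0)
    stop("dose must be >= 0 and ka, Fa, Qent > 0")
  (dose * ka * Fa / Qent) / MW * 1000   # mg/L -> uM
}

#' Periodic enterocyte inhibitor concentration profile
#'
#' Returns a function of absolute time giving the enterocyte (gut-wall)
#' concentration (uM) of a perpetrator dosed periodically: each oral dose
#' contributes [gut_inhibitor_concentration()] decaying with the
#' perpetrator's `ka`, with carryover across cycles summed in closed form.
#'
#' @param params perpetrator [compartmental_params()].
#' @param regimen perpetrator [pk_regimen()] (the maintenance cycle).
#' @param Qent enterocyte blood flow (L/h).
#' @return `function(t)` vectorised over `t` (h), in uM.
#' @export
gut_inhibitor_profile <- function(params, regimen, Qent = 18) {
  ev <- regimen$events
  ev <- ev[ev$route == "oral", , drop = FALSE]
  tau <- regimen$cycle_length
  ka <- params$ka
  acc <- 1 / (1 - exp(-ka * tau))   # periodic carryover
  I0 <- vapply(seq_len(nrow(ev)), function(i)
    gut_inhibitor_concentration(ev$amount[i], ka, params$Fa, params$MW, Qent),
    0)
  function(t) {
    out <- numeric(length(t))
    s <- t %% tau
    for (i in seq_along(I0)) {
      ds <- (s - ev$time[i]) %% tau
      out <- out + I0[i] * exp(-ka * ds) * acc
    }
    out
  }
}

#' Inhibition specification for an interaction run
#'
#' @param Ki competitive inhibition constant of the perpetrator on CYP3A4
#'   (uM).
#' @param inhibit_gut,inhibit_liver logical site toggles.  Both `FALSE` is
#'   allowed and yields exposure ratios of exactly 1.
#' @export
inhibition_spec <- function(Ki, inhibit_gut = TRUE, inhibit_liver = TRUE) {
  if (!is.numeric(Ki) || Ki <= 0) stop("'Ki' must be > 0")
  structure(list(Ki = Ki, inhibit_gut = isTRUE(inhibit_gut),
                 inhibit_liver = isTRUE(inhibit_liver)),
            class = "inhibition_spec")
}

#' Victim-drug disposition for interaction scenarios
#'
#' Bundles the victim's compartmental parameters with its absorption
#' decomposition (`Fa`, `Fg`) and the fraction of hepatic elimination
#' mediated by CYP3A4.  `Fa * Fg` must equal the parameter set's `FaFg`.
#'
#' @param params victim [compartmental_params()].
#' @param Fa,Fg fraction absorbed and baseline gut availability; default
#'   to `params$Fa` and `FaFg / Fa`.
#' @param fm_CYP3A4 fraction of hepatic elimination via CYP3A4; defaults to
#'   the value in `params` and must not be `NA`.
#' @export
victim_disposition <- function(params, Fa = params$Fa,
                               Fg = params$FaFg / params$Fa,
                               fm_CYP3A4 = params$fm_CYP3A4) {
  if (abs(Fa * Fg - params$FaFg) > 1e-12)
    stop("Fa * Fg must equal the parameter set's FaFg")
  if (Fg <= 0 || Fg > 1) stop("'Fg' must lie in (0, 1]")
  if (is.na(fm_CYP3A4))
    stop("victim 'fm_CYP3A4' is required (no silent default)")
  if (fm_CYP3A4 < 0 || fm_CYP3A4 > 1) stop("'fm_CYP3A4' must lie in [0, 1]")
  structure(list(params = params, Fa = Fa, Fg = Fg,
                 fm_CYP3A4 = fm_CYP3A4),
            class = "victim_disposition")
}

# Unbound hepatic-inlet inhibitor concentration (uM) as a periodic function
# of time, from a perpetrator steady-state simulation.  inlet = "inlet"
# adds the absorption-rate term ka*Alum/Qh to the systemic concentration;
# "systemic" uses the circulating concentration alone.
perp_inlet_fun <- function(params, ss, tau, inlet = c("inlet", "systemic")) {
  inlet <- match.arg(inlet)
  prof <- ss$profile
  states <- attr(prof, "states")
  csys <- prof$conc                                   # ng/mL
  cabs <- if (inlet == "inlet")
    params$ka * states[, "Alum"] / (params$Qh * 1000) # ng/mL
  else 0
  ctot_uM <- conc_to_uM(csys + cabs, params$MW)
  f <- stats::approxfun(prof$time, params$fu_b * ctot_uM, rule = 2)
  function(t) f(t %% tau)
}

# Per-dose gut CLint ratio under competitive inhibition by the perpetrator
# enterocyte profile.  mode "instant" evaluates at the victim dosing
# instant; "average" weights by the victim's own absorption time course.
gut_ratio_for_dose <- function(td, Ig_fun, Ki, ka_v,
                               mode = c("average", "instant")) {
  mode <- match.arg(mode)
  if (mode == "instant") return(1 / (1 + Ig_fun(td) / Ki))
  Tmax <- 14 / ka_v
  s <- seq(0, Tmax, length.out = 701)
  r <- 1 / (1 + Ig_fun(td + s) / Ki)
  w <- ka_v * exp(-ka_v * s)
  min(max(trapz_auc(s, w * r) + exp(-ka_v * Tmax) * r[length(r)], 0), 1)
}

#' Run a perpetrator-victim CYP3A4 interaction scenario
#'
#' Simulates the perpetrator to steady state, derives its unbound hepatic
#' inlet concentration over the dosing cycle and its enterocyte
#' concentration profile, then simulates the victim to steady state twice —
#' without and with inhibition — and reports exposure ratios.  Hepatic
#' inhibition scales the CYP3A4-mediated share of the victim's intrinsic
#' clearance dynamically, \eqn{CL_{int}(t) = CL_{int}[f_m/(1+I_u(t)/K_i) +
#' (1-f_m)]}; gut inhibition rescales each oral victim dose's gut
#' availability via [gut_availability()].
#'
#' @param victim a [victim_disposition()].
#' @param victim_regimen victim [pk_regimen()] (one maintenance cycle).
#' @param perpetrator perpetrator [compartmental_params()].
#' @param perp_regimen perpetrator maintenance [pk_regimen()]; its cycle
#'   length must equal the victim's.
#' @param spec an [inhibition_spec()].
#' @param perp_loading optional perpetrator loading [pk_regimen()].
#' @param offset victim dose-clock shift (h) relative to the perpetrator
#'   schedule; see [staggered_interval_scan()].
#' @param gut_model `"average"` (competitive-inhibition ratio averaged over
#'   the victim's absorption time course; default) or `"instant"`
#'   (evaluated at the victim dosing instant).
#' @param inlet `"inlet"` (systemic plus absorption-rate term; default) or
#'   `"systemic"` for the hepatic driving concentration.
#' @param Qent enterocyte blood flow (L/h).
#' @param dt,ss_tol,max_cycles steady-state simulation controls, see
#'   [simulate_steady_state()].
#' @return An object of class `ddi_result` with `auc_ratio`, `cmax_ratio`,
#'   `fg_ratio` (mean per-dose inhibited/baseline gut availability),
#'   `hepatic_clearance_ratio` (baseline over time-averaged inhibited
#'   hepatic clearance), the two `exposure_metrics`, per-dose gut
#'   availabilities and a scenario description.
#' @export
run_ddi_scenario <- function(victim, victim_regimen, perpetrator,
                             perp_regimen, spec, perp_loading = NULL,
                             offset = 0, gut_model = c("average", "instant"),
                             inlet = c("inlet", "systemic"), Qent = 18,
                             dt = 0.05, ss_tol = 1e-3, max_cycles = 80) {
  gut_model <- match.arg(gut_model); inlet <- match.arg(inlet)
  if (!inherits(victim, "victim_disposition"))
    stop("'victim' must be a victim_disposition object")
  if (!inherits(spec, "inhibition_spec"))
    stop("'spec' must be an inhibition_spec object")
  vp <- victim$params
  tau <- victim_regimen$cycle_length
  any_site <- spec$inhibit_gut || spec$inhibit_liver
  if (any_site && abs(perp_regimen$cycle_length - tau) > 1e-9)
    stop("victim and perpetrator cycle lengths must match")
  if (spec$inhibit_liver && is.na(victim$fm_CYP3A4))
    stop("victim 'fm_CYP3A4' is required for hepatic inhibition")

  clint_fun <- NULL; fg_fun <- NULL
  fg_tab <- NULL
  Iu_fun <- NULL
  if (any_site) {
    perp_ss <- simulate_steady_state(perpetrator, perp_regimen,
                                     loading = perp_loading, dt = dt,
                                     ss_tol = ss_tol,
                                     max_cycles = max_cycles)
    if (spec$inhibit_liver) {
      Iu_fun <- perp_inlet_fun(perpetrator, perp_ss, tau, inlet)
      fm <- victim$fm_CYP3A4
      CLint_v <- vp$CLint_h
      clint_fun <- function(t)
        CLint_v * (fm / (1 + Iu_fun(t) / spec$Ki) + (1 - fm))
    }
    if (spec$inhibit_gut) {
      Ig_fun <- gut_inhibitor_profile(perpetrator, perp_regimen, Qent)
      Fg0 <- victim$Fg
      ka_v <- vp$ka
      fg_fun <- function(td) {
        r <- gut_ratio_for_dose(td %% tau, Ig_fun, spec$Ki, ka_v, gut_model)
        gut_availability(Fg0, r)
      }
      fg_tab <- vapply((victim_regimen$events$time + offset) %% tau,
                       fg_fun, 0)
    }
  }

  base <- simulate_steady_state(vp, victim_regimen, shift = offset, dt = dt,
                                ss_tol = ss_tol, max_cycles = max_cycles)
  inh <- simulate_steady_state(vp, victim_regimen, shift = offset, dt = dt,
                               ss_tol = ss_tol, max_cycles = max_cycles,
                               clint_fun = clint_fun, fg_fun = fg_fun)
  mb <- exposure_metrics(base$profile, c(0, tau))
  mi <- exposure_metrics(inh$profile, c(0, tau))

  hep_ratio <- 1
  if (spec$inhibit_liver) {
    tg <- seq(0, tau, by = dt)
    hep_ratio <- hepatic_clearance(vp) /
      mean(hepatic_clearance(vp, clint_fun(tg)))
  }
  structure(list(
    auc_ratio = mi$auc / mb$auc,
    cmax_ratio = mi$cmax / mb$cmax,
    fg_ratio = if (is.null(fg_tab)) 1 else mean(fg_tab) / victim$Fg,
    hepatic_clearance_ratio = hep_ratio,
    fg_per_dose = fg_tab,
    baseline = mb, inhibited = mi,
    scenario = list(victim = vp$name, perpetrator = perpetrator$name,
                    Ki = spec$Ki, inhibit_gut = spec$inhibit_gut,
                    inhibit_liver = spec$inhibit_liver, offset = offset,
                    gut_model = gut_model, inlet = inlet)),
    class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<ddi_result> %s + %s (gut %s, liver %s, offset %g h)\n",
              s$victim, s$perpetrator, s$inhibit_gut, s$inhibit_liver,
              s$offset))
  cat(sprintf("  AUC ratio %.3f | Cmax ratio %.3f | Fg ratio %.3f | CLh ratio %.3f\n",
              x$auc_ratio, x$cmax_ratio, x$fg_ratio,
              x$hepatic_clearance_ratio))
  invisible(x)
}

#' Scan exposure ratios over staggered dosing offsets
#'
#' Reruns [run_ddi_scenario()] shifting the victim's dose clock by each
#' offset (h), quantifying how separating victim and perpetrator oral
#' doses mitigates the gut interaction.
#'
#' @inheritParams run_ddi_scenario
#' @param offsets offsets (h), each in `[0, cycle_length)`.
#' @return Data frame (`offset`, `auc_ratio`, `cmax_ratio`, `fg_ratio`)
#'   sorted by offset.
#' @export
staggered_interval_scan <- function(victim, victim_regimen, perpetrator,
                                    perp_regimen, spec, offsets, ...) {
  if (any(offsets < 0 | offsets >= victim_regimen$cycle_length))
    stop("offsets must lie in [0, cycle_length)")
  offsets <- sort(offsets)
  rows <- lapply(offsets, function(off) {
    r <- run_ddi_scenario(victim, victim_regimen, perpetrator, perp_regimen,
                          spec, offset = off, ...)
    data.frame(offset = off, auc_ratio = r$auc_ratio,
               cmax_ratio = r$cmax_ratio, fg_ratio = r$fg_ratio)
  })
  do.call(rbind, rows)
}

#' Packaged cyclosporine interaction scenarios
#'
#' Convenience wrapper reproducing the packaged study design: victim
#' cyclosporine 50 mg orally twice daily (cycle times 0 and 11 h,
#' mirroring 10:00/21:00 dosing), perpetrator either isavuconazole
#' (200 mg once daily after a 200 mg three-times-daily two-day loading
#' phase, Ki 5.48 uM) or voriconazole (30 mg twice daily at the victim's
#' dose times, packaged literature Ki), with gut and hepatic inhibition
#' separately toggleable.
#'
#' @param perpetrator `"isavuconazole"` or `"voriconazole"`.
#' @param inhibit_gut,inhibit_liver site toggles.
#' @param offset victim dose-clock shift (h).
#' @param ... passed to [run_ddi_scenario()].
#' @return A `ddi_result`.
#' @export
run_packaged_scenario <- function(perpetrator = c("isavuconazole",
                                                  "voriconazole"),
                                  inhibit_gut = TRUE, inhibit_liver = TRUE,
                                  offset = 0, ...) {
  perpetrator <- match.arg(perpetrator)
  csa <- load_drug("cyclosporine")
  victim <- victim_disposition(csa)
  vreg <- regimen_schedule(50, c(0, 11), cycle_length = 24)
  perp <- load_drug(perpetrator)
  Ki <- attr(perp, "Ki_CYP3A4_uM")
  if (perpetrator == "isavuconazole") {
    preg <- regimen_schedule(200, 0, cycle_length = 24)
    pload <- regimen_schedule(200, c(0, 8, 16), cycle_length = 24,
                              n_cycles = 2)
  } else {
    preg <- regimen_schedule(30, c(0, 11), cycle_length = 24)
    pload <- NULL
  }
  run_ddi_scenario(victim, vreg, perp, preg,
                   inhibition_spec(Ki, inhibit_gut, inhibit_liver),
                   perp_loading = pload, offset = offset, ...)
}
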