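#' Concentration-time observations for model fitting
#'
#' @param time observation times (h), non-negative.
#' @param conc observed concentrations (ng/mL), non-negative.
#' @param regimen the [pk_regimen()] under which the data were collected.
#' @param lloq,uloq assay lower/upper limits of quantitation (ng/mL).
#'   Observations outside the quantitative range are flagged (`"BQL"` /
#'   `"AQL"`), never silently dropped; the fitter excludes flagged points
#'   by default and reports how many.
#' @param truth optional `compartmental_params` that generated the data
#'   (attached by the synthetic generator for recovery tests).
#' @return An object of class `pk_observations`.
#' @export
pk_observations <- function(time, conc, regimen, lloq = NA, uloq = NA,
                            truth = NULL) {
  if (any(time < 0)) stop("observation times must be >= 0")
  if (any(conc < 0)) stop("observed concentrations must be >= 0")
  flag <- rep("OK", length(conc))
  if (!is.na(lloq)) flag[conc < lloq] <- "BQL"
  if (!is.na(uloq)) flag[conc > uloq] <- "AQL"
  structure(list(data = data.frame(time = time, conc = conc, flag = flag),
                 regimen = regimen, lloq = lloq, uloq = uloq,
                 truth = truth),
            class = "pk_observations")
}

#' @export
print.pk_observations <- function(x, ...) {
  cat("<pk_observations> n =", nrow(x$data), "(",
      sum(x$data$flag != "OK"), "flagged )\n")
  invisible(x)
}

#' Akaike information criterion for a least-squares fit
#'
#' Gaussian least-squares form \eqn{AIC = n \ln(RSS/n) + 2k} (constant
#' terms dropped), the convention used throughout this package so reported
#' values are auditable.  Adding a useless parameter (same RSS, k+1)
#' increases the value by exactly 2.
#'
#' @param n_obs number of observations used in the fit.
#' @param rss residual sum of squares (> 0; `rss = 0` returns `-Inf` with
#'   a warning).
#' @param k number of free parameters.
#' @export
aic_ls <- function(n_obs, rss, k) {
  if (n_obs <= 0) stop("'n_obs' must be > 0")
  if (rss < 0) stop("'rss' must be >= 0")
  if (rss == 0) {
    warning("rss = 0: AIC is -Inf (perfect fit)")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * k
}

#' Fit two-compartment parameters to concentration-time data
#'
#' Weighted nonlinear least squares on the closed-form multiple-dose
#' solution, with bounded Levenberg-Marquardt optimisation
#' ([minpack.lm::nls.lm]) in log-parameter space and multi-start
#' initialisation (the supplied init plus `n_starts - 1` log-uniform draws
#' within the bounds, seeded so fits are reproducible).  Two-compartment
#' least-squares surfaces are multimodal, hence the restarts.
#'
#' @param obs a [pk_observations()].
#' @param init a [compartmental_params()] supplying starting values and
#'   every non-fitted parameter.
#' @param free names of parameters to estimate; any of
#'   `"ka", "V1", "k12", "k21", "CLint_h", "CLr"`.  Others are fixed at
#'   their `init` values.
#' @param weighting `"1/y^2"` (default), `"1/y"` or `"uniform"`; weights
#'   applied to squared residuals use the observed concentrations.
#' @param lower,upper named bounds for the free parameters; default
#'   `init/100` and `init*100`.
#' @param n_starts multi-start budget.
#' @param seed RNG seed for the start draws.
#' @return An object of class `pk_fit`: `params` (estimates merged into
#'   `init`), `estimates`, `rss` (weighted), `rss_unweighted`, `n_obs`,
#'   `n_free`, `aic`, `converged`, `n_excluded` (flagged observations),
#'   `starts` (per-start RSS).  Non-convergence of every start is an
#'   explicit error, never a silent partial result.
#' @export
fit_two_compartment <- function(obs, init,
                                free = c("ka", "V1", "k12", "k21",
                                         "CLint_h"),
                                weighting = c("1/y^2", "1/y", "uniform"),
                                lower = NULL, upper = NULL,
                                n_starts = 10, seed = 1) {
  weighting <- match.arg(weighting)
  if (!inherits(obs, "pk_observations")) stop("'obs' must be pk_observations")
  allowed <- c("ka", "V1", "k12", "k21", "CLint_h", "CLr")
  if (!all(free %in% allowed))
    stop("free parameters must be among: ", paste(allowed, collapse = ", "))
  use <- obs$data$flag == "OK"
  d <- obs$data[use, , drop = FALSE]
  if (nrow(d) < length(free) + 1)
    stop("need at least n_free + 1 usable observations")
  w <- switch(weighting,
              "1/y^2" = 1 / pmax(d$conc, 1e-9),
              "1/y"   = 1 / sqrt(pmax(d$conc, 1e-9)),
              "uniform" = rep(1, nrow(d)))
  th0 <- log(unlist(init[free]))
  lo <- log(if (is.null(lower)) unlist(init[free]) / 100
            else unlist(lower[free]))
  hi <- log(if (is.null(upper)) unlist(init[free]) * 100
            else unlist(upper[free]))
  predict_conc <- function(th) {
    p <- init
    p[free] <- as.list(exp(th))
    p <- do.call(compartmental_params,
                 p[setdiff(names(p), "name")])
    analytic_profile(p, obs$regimen, d$time)$conc
  }
  resid_fn <- function(th) w * (predict_conc(th) - d$conc)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # candidate screen: the supplied init, local perturbations of it and
  # global log-uniform draws, ranked by objective value; the best
  # n_starts - 1 candidates (plus init itself) are polished with LM
  n_cand <- max(40 * length(free), 20 * n_starts)
  loc <- matrix(stats::rnorm(n_cand * length(free),
                             mean = rep(th0, each = n_cand), sd = log(3)),
                ncol = length(free))
  glob <- matrix(stats::runif(n_cand * length(free),
                              rep(lo, each = n_cand),
                              rep(hi, each = n_cand)),
                 ncol = length(free))
  cand <- rbind(loc, glob)
  cand <- pmin(pmax(cand, rep(lo, each = nrow(cand))),
               rep(hi, each = nrow(cand)))
  obj <- apply(cand, 1, function(th) sum(resid_fn(th)^2))
  cand <- cand[order(obj), , drop = FALSE]
  starts <- rbind(th0, cand[seq_len(min(n_starts - 1, nrow(cand))), ,
                            drop = FALSE])
  best <- NULL
  start_rss <- rep(NA_real_, nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(starts[i, ], lo), hi), lower = lo, upper = hi,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    rss <- sum(fit$fvec^2)
    start_rss[i] <- rss
    if (ok && (is.null(best) || rss < best$rss))
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fit_two_compartment: no start converged within the budget")
  th <- best$fit$par
  est <- stats::setNames(exp(th), free)
  p <- init; p[free] <- as.list(est)
  p <- do.call(compartmental_params, p[setdiff(names(p), "name")])
  pred <- predict_conc(th)
  structure(list(params = p, estimates = est, rss = best$rss,
                 rss_unweighted = sum((pred - d$conc)^2),
                 n_obs = nrow(d), n_free = length(free),
                 aic = aic_ls(nrow(d), best$rss, length(free)),
                 converged = TRUE, n_excluded = sum(!use),
                 weighting = weighting, starts = start_rss),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> n =", x$n_obs, "(", x$n_excluded, "excluded ) k =",
      x$n_free, "\n")
  cat("  estimates:", paste(names(x$estimates),
                            signif(x$estimates, 5), collapse = ", "), "\n")
  cat(sprintf("  weighted RSS %.6g | AIC %.4g | weighting %s\n",
              x$rss, x$aic, x$weighting))
  invisible(x)
}

#' Read/write fitting interchange files
#'
#' Observations CSV columns: `time_h`, `conc_ng_per_mL`, `flag`; fit
#' results as JSON.
#' @param path file path.
#' @param obs,x objects to write.
#' @export
write_observations_csv <- function(obs, path) {
  utils::write.csv(data.frame(time_h = obs$data$time,
                              conc_ng_per_mL = obs$data$conc,
                              flag = obs$data$flag),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
write_fit_json <- function(x, path) {
  jsonlite::write_json(list(estimates = as.list(x$estimates),
                            rss = x$rss, n_obs = x$n_obs,
                            n_free = x$n_free, aic = x$aic,
                            converged = x$converged,
                            weighting = x$weighting),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
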