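#' Dose events and repeated-dose regimens
#'
#' A `dose_event` is a single administration; a `pk_regimen` is an ordered
#' set of events repeated every `cycle_length` hours for `n_cycles` cycles.
#' Times are hours from the simulation origin; clock times (e.g. dosing at
#' 10:00 and 21:00) are converted to offsets at the boundary by the caller.
#'
#' @param amount dose (mg), non-negative.
#' @param time event time (h) within the cycle, `0 <= time < cycle_length`.
#' @param route `"oral"` or `"intravenous"`.
#' @param infusion_duration infusion length (h); 0 means bolus (ignored for
#'   oral dosing).
#' @return `dose_event()`: a one-row data frame; `pk_regimen()`: an object
#'   of class `pk_regimen`.
#' @export
dose_event <- function(amount, time, route = c("oral", "intravenous"),
                       infusion_duration = 0) {
  route <- match.arg(route)
  if (!is.numeric(amount) || amount < 0) stop("dose amount must be >= 0")
  if (!is.numeric(time) || time < 0) stop("dose time must be >= 0")
  if (infusion_duration < 0) stop("infusion_duration must be >= 0")
  data.frame(amount = amount, time = time, route = route,
             infusion_duration = infusion_duration,
             stringsAsFactors = FALSE)
}

#' @rdname dose_event
#' @param events a list of [dose_event()] rows (or a data frame of them).
#' @param cycle_length repetition period (h).
#' @param n_cycles number of cycles simulated.
#' @export
pk_regimen <- function(events, cycle_length = 24, n_cycles = 1) {
  if (is.data.frame(events)) ev <- events
  else ev <- do.call(rbind, events)
  if (nrow(ev) == 0) stop("regimen needs at least one dose event")
  if (any(ev$time >= cycle_length))
    stop("all event times must be smaller than 'cycle_length'")
  ev <- ev[order(ev$time), , drop = FALSE]
  if (n_cycles < 1) stop("'n_cycles' must be >= 1")
  structure(list(events = ev, cycle_length = cycle_length,
                 n_cycles = as.integer(n_cycles)),
            class = "pk_regimen")
}

#' Convenience constructor for a uniform oral/IV schedule
#'
#' @param amount dose per administration (mg).
#' @param times event times within a cycle (h).
#' @inheritParams dose_event
#' @inheritParams pk_regimen
#' @export
regimen_schedule <- function(amount, times, cycle_length = 24, n_cycles = 1,
                             route = "oral", infusion_duration = 0) {
  ev <- do.call(rbind, lapply(times, function(tt)
    dose_event(amount, tt, route, infusion_duration)))
  pk_regimen(ev, cycle_length, n_cycles)
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat("<pk_regimen> ", nrow(x$events), " event(s)/cycle, tau = ",
      x$cycle_length, " h x ", x$n_cycles, " cycle(s)\n", sep = "")
  print(x$events)
  invisible(x)
}

#' Expand a regimen into absolute dose times
#'
#' @param regimen a [pk_regimen()].
#' @param shift constant added to every event time (h), e.g. a staggered
#'   dosing offset.
#' @return Data frame with one row per administration over all cycles
#'   (columns `amount`, `time`, `route`, `infusion_duration`).
#' @export
expand_regimen <- function(regimen, shift = 0) {
  ev <- regimen$events
  out <- do.call(rbind, lapply(seq_len(regimen$n_cycles) - 1L, function(cy) {
    e <- ev
    e$time <- e$time + cy * regimen$cycle_length + shift
    e
  }))
  out[order(out$time), , drop = FALSE]
}

#' Total simulated duration of a regimen (h)
#' @param regimen a [pk_regimen()].
#' @export
regimen_duration <- function(regimen) regimen$cycle_length * regimen$n_cycles
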