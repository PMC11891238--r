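#' Two-compartment oral PK parameter set
#'
#' Container for the disposition parameters of a drug described by a
#' two-compartment model with first-order oral absorption, renal
#' elimination, and hepatic elimination through the well-stirred liver
#' model.  Hepatic blood clearance is derived from intrinsic clearance as
#' \deqn{CL_h = \frac{Q_h f_{u,b} CL_{int,h}}{Q_h + f_{u,b} CL_{int,h}}}
#' which is always strictly below hepatic blood flow \eqn{Q_h}.
#'
#' @param ka first-order absorption rate constant (1/h).
#' @param V1 central compartment volume (L).
#' @param k12,k21 central-peripheral distribution rate constants (1/h).
#' @param CLint_h hepatic intrinsic clearance (L/h), referred to unbound
#'   drug in blood.
#' @param CLr renal clearance (L/h).
#' @param FaFg product of fraction absorbed and gut-wall availability
#'   (dimensionless, in (0, 1]).
#' @param fu_b unbound fraction in blood (dimensionless, in (0, 1]).
#' @param MW molecular weight (g/mol), used for mass/molar conversion.
#' @param Qh hepatic blood flow (L/h); default 96.6 L/h, a standard adult
#'   value.
#' @param Fa fraction absorbed (dimensionless).  Default 1, so that
#'   `Fg = FaFg`; override if an independent estimate of Fa is available.
#' @param fm_CYP3A4 fraction of hepatic elimination mediated by CYP3A4
#'   (dimensionless, in \[0, 1\]), required for interaction scenarios;
#'   `NA` when unknown.
#' @param name optional drug name label.
#'
#' @return An object of class `compartmental_params` (a named list).
#' @seealso [hepatic_clearance()], [simulate_profile()], [load_drug()]
#' @export
compartmental_params <- function(ka, V1, k12, k21, CLint_h, CLr, FaFg,
                                 fu_b, MW, Qh = 96.6, Fa = 1,
                                 fm_CYP3A4 = NA_real_, name = NULL) {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("'", what, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  p <- list(ka = num1(ka, "ka"), V1 = num1(V1, "V1"),
            k12 = num1(k12, "k12"), k21 = num1(k21, "k21"),
            CLint_h = num1(CLint_h, "CLint_h"), CLr = num1(CLr, "CLr"),
            FaFg = num1(FaFg, "FaFg"), fu_b = num1(fu_b, "fu_b"),
            MW = num1(MW, "MW"), Qh = num1(Qh, "Qh"), Fa = num1(Fa, "Fa"),
            fm_CYP3A4 = if (is.na(fm_CYP3A4)) NA_real_
                        else num1(fm_CYP3A4, "fm_CYP3A4"),
            name = if (is.null(name)) NA_character_ else as.character(name))
  for (f in c("ka", "V1", "k12", "k21", "CLint_h", "MW", "Qh"))
    if (p[[f]] <= 0) stop("'", f, "' must be strictly positive", call. = FALSE)
  if (p$CLr < 0) stop("'CLr' must be non-negative", call. = FALSE)
  if (p$FaFg <= 0 || p$FaFg > 1) stop("'FaFg' must lie in (0, 1]", call. = FALSE)
  if (p$fu_b <= 0 || p$fu_b > 1) stop("'fu_b' must lie in (0, 1]", call. = FALSE)
  if (p$Fa <= 0 || p$Fa > 1) stop("'Fa' must lie in (0, 1]", call. = FALSE)
  if (!is.na(p$fm_CYP3A4) && (p$fm_CYP3A4 < 0 || p$fm_CYP3A4 > 1))
    stop("'fm_CYP3A4' must lie in [0, 1]", call. = FALSE)
  if (p$FaFg > p$Fa + 1e-12)
    stop("'FaFg' cannot exceed 'Fa'", call. = FALSE)
  class(p) <- "compartmental_params"
  p
}

#' @export
print.compartmental_params <- function(x, ...) {
  cat("<compartmental_params>",
      if (!is.na(x$name)) paste0(" ", x$name) else "", "\n", sep = "")
  cat(sprintf("  ka %.4g /h | V1 %.4g L | k12 %.4g /h | k21 %.4g /h\n",
              x$ka, x$V1, x$k12, x$k21))
  cat(sprintf("  CLint_h %.4g L/h | CLr %.4g L/h | CLh %.4g L/h (Qh %.4g)\n",
              x$CLint_h, x$CLr, hepatic_clearance(x), x$Qh))
  cat(sprintf("  FaFg %.3g | fu_b %.3g | MW %.5g | fm_CYP3A4 %s\n",
              x$FaFg, x$fu_b, x$MW,
              if (is.na(x$fm_CYP3A4)) "NA" else format(x$fm_CYP3A4)))
  invisible(x)
}

#' Well-stirred hepatic blood clearance
#'
#' @param params a [compartmental_params()] object.
#' @param CLint_h optional intrinsic clearance override (L/h), e.g. an
#'   inhibited value; defaults to the value stored in `params`.
#' @return Hepatic blood clearance (L/h), always `< Qh`.
#' @export
hepatic_clearance <- function(params, CLint_h = params$CLint_h) {
  fuCL <- params$fu_b * CLint_h
  params$Qh * fuCL / (params$Qh + fuCL)
}

#' Hepatic availability (fraction escaping first pass)
#' @inheritParams hepatic_clearance
#' @return `1 - CLh/Qh`, in (0, 1].
#' @export
hepatic_availability <- function(params, CLint_h = params$CLint_h) {
  1 - hepatic_clearance(params, CLint_h) / params$Qh
}

#' Total systemic clearance and oral bioavailability
#'
#' `total_clearance()` is `CLh + CLr`; `oral_bioavailability()` is
#' `FaFg * Fh` with `Fh` from [hepatic_availability()].
#' @inheritParams hepatic_clearance
#' @export
total_clearance <- function(params) hepatic_clearance(params) + params$CLr

#' @rdname total_clearance
#' @export
oral_bioavailability <- function(params) {
  params$FaFg * hepatic_availability(params)
}

#' Read or write a drug parameter file
#'
#' Drug parameter files are JSON with a `parameters` object (keys matching
#' [compartmental_params()] arguments), a sibling `units` object and a
#' `source` object tagging each value (e.g. printed-in-paper,
#' packaged-literature, calibrated, synthetic).
#'
#' @param path path to a JSON drug file.
#' @return For `read_drug_params()`, a `compartmental_params` object with
#'   the `units` and `source` metadata attached as attributes.
#' @export
read_drug_params <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (is.null(j$parameters)) stop("drug file lacks a 'parameters' object")
  pars <- j$parameters
  fm <- if (is.null(pars$fm_CYP3A4)) NA_real_ else pars$fm_CYP3A4
  p <- compartmental_params(ka = pars$ka, V1 = pars$V1, k12 = pars$k12,
                            k21 = pars$k21, CLint_h = pars$CLint_h,
                            CLr = pars$CLr, FaFg = pars$FaFg,
                            fu_b = pars$fu_b, MW = pars$MW,
                            Qh = if (is.null(pars$Qh)) 96.6 else pars$Qh,
                            Fa = if (is.null(pars$Fa)) 1 else pars$Fa,
                            fm_CYP3A4 = fm, name = j$name)
  attr(p, "units") <- j$units
  attr(p, "source") <- j$source
  attr(p, "Ki_CYP3A4_uM") <- j$Ki_CYP3A4_uM
  p
}

#' @rdname read_drug_params
#' @param params a `compartmental_params` object.
#' @param units,source optional named lists of unit strings / provenance
#'   tags written alongside the parameters.
#' @param Ki_CYP3A4_uM optional competitive inhibition constant on CYP3A4
#'   (micromolar) stored with the drug.
#' @export
write_drug_params <- function(params, path, units = NULL, source = NULL,
                              Ki_CYP3A4_uM = NULL) {
  flds <- c("ka", "V1", "k12", "k21", "CLint_h", "CLr", "FaFg", "fu_b",
            "MW", "Qh", "Fa", "fm_CYP3A4")
  j <- list(name = params$name, parameters = params[flds],
            units = units, source = source, Ki_CYP3A4_uM = Ki_CYP3A4_uM)
  jsonlite::write_json(j[!vapply(j, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Load a packaged drug parameter set
#'
#' The package ships three drug files under `extdata/drugs/`:
#' `"isavuconazole"` (two-compartment parameters from the published fit;
#' `fu_b` and `Qh` are packaged literature/standard constants),
#' `"cyclosporine"` and `"voriconazole"` (synthetic literature-informed
#' reconstructions; the cyclosporine gut availability `FaFg = 0.28` and the
#' voriconazole clearance calibrated to a 1.0 ug/mL trough at 30 mg twice
#' daily are the published hard constraints).  Every non-published value is
#' tagged in the file's `source` object.
#'
#' @param drug one of `"isavuconazole"`, `"cyclosporine"`, `"voriconazole"`.
#' @return A `compartmental_params` object (see [read_drug_params()]).
#' @export
load_drug <- function(drug = c("isavuconazole", "cyclosporine",
                               "voriconazole")) {
  drug <- match.arg(drug)
  path <- system.file("extdata", "drugs", paste0(drug, ".json"),
                      package = "pbpkddi", mustWork = TRUE)
  read_drug_params(path)
}

#' Convert between mass and molar concentration units
#'
#' Internal canonical concentration unit is ng/mL.  `conc_to_uM()` converts
#' ng/mL to micromolar; `auc_convert()` converts an AUC between the
#' canonical ng·h/mL and other reporting units.  Note ng/mL equals ug/L, so
#' an AUC in ng·h/mL is numerically an AUC in ug·h/L.
#'
#' @param x numeric vector.
#' @param MW molecular weight (g/mol).
#' @export
conc_to_uM <- function(x, MW) x / MW

#' @rdname conc_to_uM
#' @param from,to units among `"ng.h/mL"`, `"ug.h/L"`, `"ng.h/L"`,
#'   `"ug.h/mL"`.
#' @export
auc_convert <- function(x, from = "ng.h/mL", to = "ng.h/L") {
  scale <- c("ng.h/mL" = 1, "ug.h/L" = 1, "ng.h/L" = 1e-3, "ug.h/mL" = 1e3)
  if (!from %in% names(scale) || !to %in% names(scale))
    stop("unknown AUC unit")
  x * scale[[from]] / scale[[to]]
}
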