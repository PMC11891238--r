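#' Concentration/dose (C/D) ratio
#'
#' Therapeutic-drug-monitoring index: blood level divided by the
#' weight-normalised daily dose,
#' \deqn{C/D = \frac{C\ (ng/mL)}{\mathrm{daily\ dose}\ (mg/day)/\mathrm{weight}\ (kg)}}
#' in (ng/mL)/(mg/kg).  Levels outside the assay quantitative range
#' (default 25.0-500.0 ng/mL) are still computed but flagged.
#'
#' @param conc blood level (ng/mL).
#' @param daily_dose daily dose (mg/day), strictly positive.
#' @param weight body weight (kg), strictly positive.
#' @param assay_range quantitative range of the assay (ng/mL).
#' @return List with `value` ((ng/mL)/(mg/kg)) and `flag` (`"OK"`,
#'   `"BQL"` below range, `"AQL"` above range).
#' @export
cd_ratio <- function(conc, daily_dose, weight,
                     assay_range = c(25.0, 500.0)) {
  if (conc < 0) stop("'conc' must be >= 0")
  if (daily_dose <= 0) stop("'daily_dose' must be > 0: C/D is undefined")
  if (weight <= 0) stop("'weight' must be > 0")
  flag <- if (conc < assay_range[1]) "BQL"
          else if (conc > assay_range[2]) "AQL" else "OK"
  list(value = conc / (daily_dose / weight), flag = flag)
}

#' Estimated GFR, Japanese serum-creatinine equation
#'
#' \deqn{eGFR = 194 \times SCr^{-1.094} \times age^{-0.287}
#'   (\times 0.739\ \mathrm{for\ females})}
#' in mL/min/1.73 m^2; a pure power law, monotone decreasing in both
#' serum creatinine and age.
#'
#' @param scr serum creatinine (mg/dL), strictly positive.
#' @param age age (years), strictly positive.
#' @param sex `"male"` or `"female"`.
#' @return eGFR (mL/min/1.73 m^2).
#' @export
egfr_japanese <- function(scr, age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(scr <= 0)) stop("'scr' must be > 0")
  if (any(age <= 0)) stop("'age' must be > 0")
  194 * scr^(-1.094) * age^(-0.287) * if (sex == "female") 0.739 else 1
}

#' Compute TDM metrics over a timeline table
#'
#' @param timeline data frame with columns `date`, `conc_ng_per_mL`,
#'   `daily_dose_mg`, `weight_kg`, `scr_mg_per_dL`, `sex`, `age` (the
#'   layout produced by [case_timeline_fixture()]); dose-unknown rows
#'   (`NA` dose) yield `NA` C/D.
#' @return The timeline with `cd_ratio`, `cd_flag` and `egfr` columns
#'   appended.
#' @export
tdm_metrics <- function(timeline) {
  n <- nrow(timeline)
  cd <- rep(NA_real_, n); fl <- rep(NA_character_, n); eg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(timeline$daily_dose_mg[i]) &&
        !is.na(timeline$conc_ng_per_mL[i])) {
      r <- cd_ratio(timeline$conc_ng_per_mL[i], timeline$daily_dose_mg[i],
                    timeline$weight_kg[i])
      cd[i] <- r$value; fl[i] <- r$flag
    }
    if (!is.na(timeline$scr_mg_per_dL[i]))
      eg[i] <- egfr_japanese(timeline$scr_mg_per_dL[i], timeline$age[i],
                             timeline$sex[i])
  }
  cbind(timeline, cd_ratio = cd, cd_flag = fl, egfr = eg)
}
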