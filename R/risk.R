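# 10-year cardiovascular risk scores.
#
# Two sex-specific proportional-hazards risk profiles are implemented in
# their continuous (survival-model) form: the Framingham general-CVD
# score (lipid-based profile) and the pooled cohort equations (PCE) for
# hard atherosclerotic CVD, white/other coefficient set. Both follow
# risk = 1 - S0 ^ exp(LP - meanLP) with published coefficients held in
# lookup tables. Other-ancestry PCE coefficient slots exist as data but
# are untested here.

# Framingham general CVD, lipid-based coefficients (log-scale terms).
.frs_coef <- list(
  female = list(
    log_age = 2.32888, log_tc = 1.20904, log_hdl = -0.70833,
    log_sbp_untreated = 2.76157, log_sbp_treated = 2.82263,
    smoker = 0.52873, diabetes = 0.69154,
    mean_lp = 26.1931, s0 = 0.95012
  ),
  male = list(
    log_age = 3.06117, log_tc = 1.12370, log_hdl = -0.93263,
    log_sbp_untreated = 1.93303, log_sbp_treated = 1.99881,
    smoker = 0.65451, diabetes = 0.57367,
    mean_lp = 23.9802, s0 = 0.88936
  )
)

# Pooled cohort equations, white/other coefficient set.
.pce_coef <- list(
  white = list(
    female = list(
      ln_age = -29.799, ln_age_sq = 4.884,
      ln_tc = 13.540, ln_age_ln_tc = -3.114,
      ln_hdl = -13.578, ln_age_ln_hdl = 3.149,
      ln_sbp_treated = 2.019, ln_sbp_untreated = 1.957,
      smoker = 7.574, ln_age_smoker = -1.665, diabetes = 0.661,
      mean_lp = -29.18, s0 = 0.9665
    ),
    male = list(
      ln_age = 12.344, ln_age_sq = 0,
      ln_tc = 11.853, ln_age_ln_tc = -2.664,
      ln_hdl = -7.990, ln_age_ln_hdl = 1.769,
      ln_sbp_treated = 1.797, ln_sbp_untreated = 1.764,
      smoker = 7.837, ln_age_smoker = -1.795, diabetes = 0.658,
      mean_lp = 61.18, s0 = 0.9144
    )
  )
)

.check_profile <- function(profile, context) {
  needed <- c("age", "sex", "tc", "hdl", "sbp", "treated_htn",
              "diabetes", "smoker")
  check_inputs(profile, needed, positive = c("tc", "hdl", "sbp"),
               context = context)
  if (anyNA(profile$age) || anyNA(profile$treated_htn) ||
      anyNA(profile$diabetes) || anyNA(profile$smoker))
    stop(context, ": age and the binary fields must be non-missing",
         call. = FALSE)
  if (any(profile$tc <= profile$hdl))
    stop(context, ": total cholesterol must exceed HDL-C", call. = FALSE)
  if (any(profile$sbp < 70 | profile$sbp > 250))
    stop(context, ": sbp outside [70, 250] mmHg", call. = FALSE)
  invisible(TRUE)
}

#' 10-year Framingham general cardiovascular risk
#'
#' Continuous Framingham risk from the sex-specific lipid-based survival
#' profile: `risk = 1 - S0^exp(LP - meanLP)` with log-transformed age,
#' total cholesterol, HDL-C and systolic blood pressure (separate
#' coefficients for treated/untreated pressure) plus smoking and
#' diabetes indicators.
#'
#' The score is validated for ages 30-74; outside that window the value
#' is still computed but flagged via the `"out_of_range"` attribute.
#'
#' @param profile Data frame with columns `age` (years), `sex` (F/M),
#'   `tc` and `hdl` (mg/dl), `sbp` (mmHg), and logicals `treated_htn`,
#'   `diabetes`, `smoker`. Use `mmol_per_l = TRUE` if lipids arrive in
#'   mmol/l (multiplied by 38.67).
#' @param mmol_per_l Logical; convert `tc`/`hdl` from mmol/l to mg/dl.
#' @return Numeric vector of 10-year risk probabilities in (0, 1), with
#'   attribute `out_of_range` marking ages outside the validated window.
#' @export
frs_10yr <- function(profile, mmol_per_l = FALSE) {
  if (mmol_per_l) {
    profile$tc <- profile$tc * 38.67
    profile$hdl <- profile$hdl * 38.67
  }
  .check_profile(profile, "frs_10yr")
  female <- is_female(profile$sex)
  lp <- numeric(nrow(profile))
  for (grp in c("female", "male")) {
    idx <- if (grp == "female") female else !female
    if (!any(idx)) next
    cf <- .frs_coef[[grp]]
    p <- profile[idx, , drop = FALSE]
    lp[idx] <- cf$log_age * log(p$age) +
      cf$log_tc * log(p$tc) + cf$log_hdl * log(p$hdl) +
      ifelse(p$treated_htn, cf$log_sbp_treated, cf$log_sbp_untreated) * log(p$sbp) +
      cf$smoker * p$smoker + cf$diabetes * p$diabetes - cf$mean_lp
  }
  s0 <- ifelse(female, .frs_coef$female$s0, .frs_coef$male$s0)
  risk <- 1 - s0^exp(lp)
  attr(risk, "out_of_range") <- profile$age < 30 | profile$age > 74
  risk
}

#' 10-year pooled cohort equation (hard ASCVD) risk
#'
#' The ACC/AHA pooled cohort equations for 10-year hard atherosclerotic
#' CVD risk, white/other coefficient set (the race term is irrelevant in
#' a European-ancestry cohort). Uses natural-log terms with
#' age-interaction coefficients per the published sex-specific tables.
#'
#' Validated age window 40-79; values outside are computed but flagged
#' via the `"out_of_range"` attribute.
#'
#' @inheritParams frs_10yr
#' @return Numeric vector of 10-year risk probabilities in (0, 1), with
#'   attribute `out_of_range`.
#' @export
pce_10yr <- function(profile, mmol_per_l = FALSE) {
  if (mmol_per_l) {
    profile$tc <- profile$tc * 38.67
    profile$hdl <- profile$hdl * 38.67
  }
  .check_profile(profile, "pce_10yr")
  female <- is_female(profile$sex)
  lp <- numeric(nrow(profile))
  for (grp in c("female", "male")) {
    idx <- if (grp == "female") female else !female
    if (!any(idx)) next
    cf <- .pce_coef$white[[grp]]
    p <- profile[idx, , drop = FALSE]
    la <- log(p$age); ltc <- log(p$tc); lhdl <- log(p$hdl); lsbp <- log(p$sbp)
    lp[idx] <- cf$ln_age * la + cf$ln_age_sq * la^2 +
      cf$ln_tc * ltc + cf$ln_age_ln_tc * la * ltc +
      cf$ln_hdl * lhdl + cf$ln_age_ln_hdl * la * lhdl +
      ifelse(p$treated_htn, cf$ln_sbp_treated, cf$ln_sbp_untreated) * lsbp +
      cf$smoker * p$smoker + cf$ln_age_smoker * la * p$smoker +
      cf$diabetes * p$diabetes - cf$mean_lp
  }
  s0 <- ifelse(female, .pce_coef$white$female$s0, .pce_coef$white$male$s0)
  risk <- 1 - s0^exp(lp)
  attr(risk, "out_of_range") <- profile$age < 40 | profile$age > 79
  risk
}

#' Dichotomize a continuous risk at a cutoff
#'
#' Maps a risk probability to `"high"` iff it strictly exceeds the
#' cutoff (default 5%), `"low"` otherwise; a risk exactly at the cutoff
#' is `"low"`. The strict inequality is a documented convention.
#'
#' @param risk Numeric vector of probabilities.
#' @param cutoff Scalar in (0, 1); default `0.05`.
#' @return Logical vector, `TRUE` = high risk.
#' @export
dichotomize_risk <- function(risk, cutoff = 0.05) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0, cutoff < 1)
  as.vector(risk > cutoff)
}

#' Append FRS/PCE risks and high-risk flags to a cohort table
#'
#' @param cohort Data frame with the risk-factor columns of [frs_10yr()].
#' @param cutoff High-risk cutoff passed to [dichotomize_risk()].
#' @param mmol_per_l Lipid unit conversion flag.
#' @return `cohort` with appended `frs_10yr`, `pce_10yr`, `frs_high`,
#'   `pce_high` and `risk_age_out_of_range` columns.
#' @export
risk_table <- function(cohort, cutoff = 0.05, mmol_per_l = FALSE) {
  frs <- frs_10yr(cohort, mmol_per_l = mmol_per_l)
  pce <- pce_10yr(cohort, mmol_per_l = mmol_per_l)
  cohort$frs_10yr <- as.vector(frs)
  cohort$pce_10yr <- as.vector(pce)
  cohort$frs_high <- dichotomize_risk(cohort$frs_10yr, cutoff)
  cohort$pce_high <- dichotomize_risk(cohort$pce_10yr, cutoff)
  cohort$risk_age_out_of_range <-
    attr(frs, "out_of_range") | attr(pce, "out_of_range")
  cohort
}
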