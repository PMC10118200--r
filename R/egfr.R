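# Estimated glomerular filtration rate (eGFR) equations.
#
# Six estimating equations are provided: the 4- and 6-variable MDRD study
# equations (IDMS-traceable constants by default), the 2009 creatinine-based
# CKD-EPI equation, the 2012 cystatin-C-based CKD-EPI equation, and the 2021
# race-free CKD-EPI equations (creatinine, and creatinine + cystatin C).
# Coefficients are kept in lookup tables (one per equation) rather than
# inline so the transcription from the primary sources is auditable.

# Per-equation coefficient tables. kappa is the sex-specific creatinine
# knot (mg/dl); alpha the below-knot exponent; beta the above-knot
# exponent; agebase the per-year multiplicative age decay.
.egfr_coef <- list(
  ckdepi_cre_2021 = list(
    constant = 142, kappa = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.241, male = -0.302), beta = -1.200,
    agebase = 0.9938, female_mult = 1.012, black_mult = 1
  ),
  ckdepi_cre_2009 = list(
    constant = 141, kappa = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.329, male = -0.411), beta = -1.209,
    agebase = 0.993, female_mult = 1.018, black_mult = 1.159
  ),
  ckdepi_cys_2012 = list(
    constant = 133, kappa_cys = 0.8,
    alpha_cys = -0.499, beta_cys = -1.328,
    agebase = 0.996, female_mult = 0.932, black_mult = 1
  ),
  ckdepi_crecys_2021 = list(
    constant = 135, kappa = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.219, male = -0.144), beta = -0.544,
    kappa_cys = 0.8, alpha_cys = -0.323, beta_cys = -0.778,
    agebase = 0.9961, female_mult = 0.963, black_mult = 1
  ),
  mdrd4 = list(
    constant = c(IDMS = 175, other = 186.3),
    scr_exp = -1.154, age_exp = -0.203,
    female_mult = 0.742, black_mult = 1.212
  ),
  mdrd6 = list(
    constant = c(IDMS = 161.5, other = 170),
    scr_exp = -0.999, age_exp = -0.176, bun_exp = -0.170, alb_exp = 0.318,
    female_mult = 0.762, black_mult = 1.180
  )
)

#' Assemble and validate a kidney marker panel
#'
#' Bundles the raw serum markers and demographics used by the eGFR
#' equations into a validated data frame. Units follow routine clinical
#' reporting: creatinine, uric acid and blood urea nitrogen in mg/dl,
#' cystatin C in mg/l, albumin in g/dl. No unit sniffing is performed; set
#' `creatinine_umol = TRUE` if creatinine arrives in micromol/l (divides
#' by 88.4).
#'
#' @param scr Serum creatinine, mg/dl (> 0).
#' @param cys Cystatin C, mg/l (> 0).
#' @param bun Blood urea nitrogen, mg/dl (> 0).
#' @param ua Uric acid, mg/dl (> 0).
#' @param age Age in years, within \[18, 120\].
#' @param sex Sex, coded `"F"`/`"M"` (or female/male, or 0/1 with 1 = female).
#' @param alb Serum albumin, g/dl; may be `NA` (the 6-variable MDRD
#'   equation then refuses to compute).
#' @param black_race Logical; race indicator used by the 2009 CKD-EPI and
#'   MDRD equations. Defaults to `FALSE`.
#' @param creatinine_umol Logical; if `TRUE`, `scr` is converted from
#'   micromol/l to mg/dl.
#' @return A `data.frame` of class `"marker_panel"` with columns
#'   `scr, cys, bun, ua, alb, age, sex, black_race` (sex as `"F"`/`"M"`).
#' @export
marker_panel <- function(scr, cys, bun, ua, age, sex, alb = NA_real_,
                         black_race = FALSE, creatinine_umol = FALSE) {
  if (creatinine_umol) scr <- scr / 88.4
  n <- length(scr)
  female <- is_female(sex)
  panel <- data.frame(
    scr = scr, cys = cys, bun = bun, ua = ua,
    alb = rep_len(as.numeric(alb), n),
    age = age, sex = ifelse(female, "F", "M"),
    black_race = rep_len(as.logical(black_race), n),
    stringsAsFactors = FALSE
  )
  check_inputs(panel, c("scr", "cys", "bun", "ua", "age"),
               positive = c("scr", "cys", "bun", "ua"),
               context = "marker_panel")
  if (any(panel$age < 18 | panel$age > 120, na.rm = TRUE))
    stop("marker_panel: age must lie in [18, 120]", call. = FALSE)
  ok_alb <- is.na(panel$alb) | panel$alb > 0
  if (!all(ok_alb))
    stop("marker_panel: alb must be > 0 when present", call. = FALSE)
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

# Shared piecewise CKD-EPI kernel for a single marker:
# min(x/kappa, 1)^alpha * max(x/kappa, 1)^beta
.ckdepi_piece <- function(x, kappa, alpha, beta) {
  pmin(x / kappa, 1)^alpha * pmax(x / kappa, 1)^beta
}

.sex_pick <- function(v, female) ifelse(female, v[["female"]], v[["male"]])

#' CKD-EPI 2021 race-free creatinine eGFR
#'
#' The 2021 refit of the creatinine-based CKD-EPI equation without a race
#' coefficient: `142 * min(scr/k, 1)^a * max(scr/k, 1)^-1.200 *
#' 0.9938^age * 1.012[if female]`, with sex-specific knot `k` (0.7
#' female / 0.9 male) and below-knot exponent `a` (-0.241 / -0.302).
#'
#' @param panel A data frame with columns `scr`, `age`, `sex` (see
#'   [marker_panel()]).
#' @return Numeric vector of eGFR in ml/min/1.73m^2.
#' @export
egfr_ckdepi_cre_2021 <- function(panel) {
  check_inputs(panel, c("scr", "age", "sex"), positive = "scr",
               context = "egfr_ckdepi_cre_2021")
  cf <- .egfr_coef$ckdepi_cre_2021
  female <- is_female(panel$sex)
  cf$constant *
    .ckdepi_piece(panel$scr, .sex_pick(cf$kappa, female),
                  .sex_pick(cf$alpha, female), cf$beta) *
    cf$agebase^panel$age *
    ifelse(female, cf$female_mult, 1)
}

#' CKD-EPI 2009 creatinine eGFR
#'
#' The 2009 creatinine-based CKD-EPI equation. Includes the original race
#' multiplier (1.159), applied only when `black_race` is `TRUE`; in a
#' European-ancestry cohort the flag is uniformly `FALSE` and the
#' multiplier never fires, but it is implemented so the equation matches
#' its published form.
#'
#' @inheritParams egfr_ckdepi_cre_2021
#' @return Numeric vector of eGFR in ml/min/1.73m^2.
#' @export
egfr_ckdepi_cre_2009 <- function(panel) {
  check_inputs(panel, c("scr", "age", "sex"), positive = "scr",
               context = "egfr_ckdepi_cre_2009")
  cf <- .egfr_coef$ckdepi_cre_2009
  female <- is_female(panel$sex)
  black <- if ("black_race" %in% names(panel)) isTRUE_vec(panel$black_race) else FALSE
  cf$constant *
    .ckdepi_piece(panel$scr, .sex_pick(cf$kappa, female),
                  .sex_pick(cf$alpha, female), cf$beta) *
    cf$agebase^panel$age *
    ifelse(female, cf$female_mult, 1) *
    ifelse(black, cf$black_mult, 1)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' CKD-EPI 2012 cystatin C eGFR
#'
#' The cystatin-C-based CKD-EPI equation: piecewise in `cys/0.8` with
#' exponents -0.499 (below) and -1.328 (above), age decay 0.996 per year,
#' female multiplier 0.932. No race term.
#'
#' @param panel A data frame with columns `cys`, `age`, `sex`.
#' @return Numeric vector of eGFR in ml/min/1.73m^2.
#' @export
egfr_ckdepi_cys_2012 <- function(panel) {
  check_inputs(panel, c("cys", "age", "sex"), positive = "cys",
               context = "egfr_ckdepi_cys_2012")
  cf <- .egfr_coef$ckdepi_cys_2012
  female <- is_female(panel$sex)
  cf$constant *
    .ckdepi_piece(panel$cys, cf$kappa_cys, cf$alpha_cys, cf$beta_cys) *
    cf$agebase^panel$age *
    ifelse(female, cf$female_mult, 1)
}

#' CKD-EPI 2021 race-free creatinine + cystatin C eGFR
#'
#' The 2021 race-free combined equation, double-piecewise in `scr/k`
#' (knot 0.7 female / 0.9 male) and `cys/0.8`.
#'
#' @param panel A data frame with columns `scr`, `cys`, `age`, `sex`.
#' @return Numeric vector of eGFR in ml/min/1.73m^2.
#' @export
egfr_ckdepi_crecys_2021 <- function(panel) {
  check_inputs(panel, c("scr", "cys", "age", "sex"),
               positive = c("scr", "cys"),
               context = "egfr_ckdepi_crecys_2021")
  cf <- .egfr_coef$ckdepi_crecys_2021
  female <- is_female(panel$sex)
  cf$constant *
    .ckdepi_piece(panel$scr, .sex_pick(cf$kappa, female),
                  .sex_pick(cf$alpha, female), cf$beta) *
    .ckdepi_piece(panel$cys, cf$kappa_cys, cf$alpha_cys, cf$beta_cys) *
    cf$agebase^panel$age *
    ifelse(female, cf$female_mult, 1)
}

#' 4-variable MDRD study equation
#'
#' Power-law eGFR from creatinine, age, sex and race. `method = "IDMS"`
#' (default) uses the constant 175 for IDMS-standardized creatinine;
#' `"other"` uses the original 186.3.
#'
#' @inheritParams egfr_ckdepi_cre_2021
#' @param method `"IDMS"` or `"other"` calibration of the constant.
#' @return Numeric vector of eGFR in ml/min/1.73m^2.
#' @export
egfr_mdrd4 <- function(panel, method = c("IDMS", "other")) {
  method <- match.arg(method)
  check_inputs(panel, c("scr", "age", "sex"), positive = "scr",
               context = "egfr_mdrd4")
  cf <- .egfr_coef$mdrd4
  female <- is_female(panel$sex)
  black <- if ("black_race" %in% names(panel)) isTRUE_vec(panel$black_race) else FALSE
  cf$constant[[method]] *
    panel$scr^cf$scr_exp * panel$age^cf$age_exp *
    ifelse(female, cf$female_mult, 1) *
    ifelse(black, cf$black_mult, 1)
}

#' 6-variable MDRD study equation
#'
#' Adds blood urea nitrogen and serum albumin to the MDRD power law.
#' Albumin must be present: a missing `alb` raises an explicit error
#' rather than returning `NaN`.
#'
#' @inheritParams egfr_mdrd4
#' @return Numeric vector of eGFR in ml/min/1.73m^2.
#' @export
egfr_mdrd6 <- function(panel, method = c("IDMS", "other")) {
  method <- match.arg(method)
  check_inputs(panel, c("scr", "bun", "alb", "age", "sex"),
               positive = c("scr", "bun", "alb"),
               context = "egfr_mdrd6")
  cf <- .egfr_coef$mdrd6
  female <- is_female(panel$sex)
  black <- if ("black_race" %in% names(panel)) isTRUE_vec(panel$black_race) else FALSE
  cf$constant[[method]] *
    panel$scr^cf$scr_exp * panel$age^cf$age_exp *
    panel$bun^cf$bun_exp * panel$alb^cf$alb_exp *
    ifelse(female, cf$female_mult, 1) *
    ifelse(black, cf$black_mult, 1)
}

#' Append all six eGFR estimates to a cohort table
#'
#' Computes the six eGFR columns row-wise, preserving row order. Rows
#' with a missing or non-positive marker required by a given equation get
#' `NA` in that equation's column and are recorded in the
#' `egfr_incomplete` flag column; they are never dropped silently.
#'
#' @param cohort A data frame with columns `scr, cys, bun, ua, age, sex`
#'   and optionally `alb`, `black_race`.
#' @param mdrd_method Calibration passed to the MDRD equations.
#' @return `cohort` with appended columns `egfr_ckdepi_cre_2009`,
#'   `egfr_ckdepi_cre_2021`, `egfr_ckdepi_cys_2012`,
#'   `egfr_ckdepi_crecys_2021`, `egfr_mdrd4`, `egfr_mdrd6`, and a logical
#'   `egfr_incomplete`.
#' @export
egfr_table <- function(cohort, mdrd_method = "IDMS") {
  stopifnot(is.data.frame(cohort))
  needed <- c("scr", "cys", "bun", "ua", "age", "sex")
  miss <- setdiff(needed, names(cohort))
  if (length(miss))
    stop("egfr_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"alb" %in% names(cohort)) cohort$alb <- NA_real_

  eqs <- list(
    egfr_ckdepi_cre_2009   = list(f = egfr_ckdepi_cre_2009,   req = "scr"),
    egfr_ckdepi_cre_2021   = list(f = egfr_ckdepi_cre_2021,   req = "scr"),
    egfr_ckdepi_cys_2012   = list(f = egfr_ckdepi_cys_2012,   req = "cys"),
    egfr_ckdepi_crecys_2021 = list(f = egfr_ckdepi_crecys_2021, req = c("scr", "cys")),
    egfr_mdrd4             = list(f = egfr_mdrd4,             req = "scr"),
    egfr_mdrd6             = list(f = egfr_mdrd6,             req = c("scr", "bun", "alb"))
  )
  incomplete <- rep(FALSE, nrow(cohort))
  for (nm in names(eqs)) {
    req <- eqs[[nm]]$req
    ok <- Reduce(`&`, lapply(req, function(cl) {
      v <- cohort[[cl]]
      !is.na(v) & is.finite(v) & v > 0
    })) & !is.na(cohort$age)
    out <- rep(NA_real_, nrow(cohort))
    if (any(ok)) {
      args <- list(cohort[ok, , drop = FALSE])
      if (grepl("mdrd", nm)) args$method <- mdrd_method
      out[ok] <- do.call(eqs[[nm]]$f, args)
    }
    incomplete <- incomplete | !ok
    cohort[[nm]] <- out
  }
  cohort$egfr_incomplete <- incomplete
  cohort
}
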