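# Synthetic two-set cohort generator.
#
# Emulates the study design the analysis assumes: a model-building set
# (baseline kidney markers only) and a longitudinal set (baseline markers
# plus ~10-year follow-up cardiovascular risk factors). Markers are
# generated from a one-factor structure: eta ~ N(0,1) is the latent
# kidney function (higher = better), each standardized indicator is
# lambda * eta + age/sex effects + noise with total unit variance, then
# affinely mapped to the configured means/SDs. Follow-up risk factors
# depend on follow-up age, sex and -eta (worse kidney function -> worse
# risk profile) at a configurable coupling strength.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: set
#' sizes 647 (model-building) and 670 (longitudinal); age means/SDs
#' 49.4 (19.1) and 40.2 (13.5) with 57.8% / 55.3% women; marker
#' means/SDs per set (creatinine 0.86/0.17 and 0.85/0.15 mg/dl, uric
#' acid 5.46/1.63 and 5.18/1.31 mg/dl, urea nitrogen 17.5/5.1 and
#' 16.3/4.1 mg/dl, cystatin C 0.83/0.25 and 0.75/0.13 mg/l, albumin
#' 4.72/0.34 and 4.76/0.33 g/dl); directly generated eGFR indicators at
#' 95.0/19.4 (creatinine-based) and 100.7/24.5 (cystatin-based)
#' ml/min/1.73m^2 in the building set, 100.8/16.1 and 111.3/15.7 in the
#' longitudinal set.
#'
#' Loadings are on the latent-function scale: raw markers load
#' negatively (higher marker = worse function), direct eGFR indicators
#' positively.
#'
#' @param n_building,n_longitudinal Set sizes (>= 50).
#' @param loadings Named loadings on the latent function factor for
#'   `scr`, `cys`, `ua`, `bun` and (direct mode) `egfr_ckdepi_cre_2021`,
#'   `egfr_ckdepi_cys_2012`; absolute values < 1.
#' @param covariate_effects Named list per indicator of standardized
#'   age/sex effects `c(age = , male = )`, or `NULL` to disable.
#' @param direct_egfr Logical; if `TRUE` the two model-2 eGFR indicator
#'   columns are generated directly from the factor structure instead of
#'   being computed from synthetic creatinine/cystatin via the eGFR
#'   equations (the remaining four eGFR columns are always computed).
#' @param coupling Strength (>= 0) of the latent-function effect on the
#'   follow-up risk factors; 0 decouples them entirely.
#' @param age_range Truncation bounds for baseline age.
#' @param marker_stats Optional replacement for the per-set mean/sd
#'   table (same shape as the default).
#' @param seed Default seed used by [generate_cohort()].
#' @return Object of class `"cohort_config"` (a list).
#' @export
cohort_config <- function(n_building = 647L, n_longitudinal = 670L,
                          loadings = c(scr = -0.757, cys = -0.597,
                                       ua = -0.597, bun = -0.638,
                                       egfr_ckdepi_cre_2021 = 0.889,
                                       egfr_ckdepi_cys_2012 = 0.856),
                          covariate_effects = default_covariate_effects(),
                          direct_egfr = FALSE,
                          coupling = 1,
                          age_range = c(18, 90),
                          marker_stats = NULL,
                          seed = 1L) {
  if (n_building < 50 || n_longitudinal < 50)
    stop("set sizes must be >= 50", call. = FALSE)
  if (any(abs(loadings) >= 1))
    stop("|loadings| must be < 1", call. = FALSE)
  if (coupling < 0) stop("coupling must be >= 0", call. = FALSE)
  if (is.null(marker_stats)) marker_stats <- default_marker_stats()
  # admissibility: residual variance must stay positive
  for (nm in names(loadings)) {
    ce <- covariate_effects[[nm]]
    extra <- if (is.null(ce)) 0 else sum(ce^2)
    if (loadings[[nm]]^2 + extra >= 1)
      stop(sprintf("inadmissible config for '%s': loading^2 + covariate effects >= 1", nm),
           call. = FALSE)
  }
  cfg <- list(
    n_building = as.integer(n_building),
    n_longitudinal = as.integer(n_longitudinal),
    loadings = loadings,
    covariate_effects = covariate_effects,
    direct_egfr = direct_egfr,
    coupling = coupling,
    age_range = age_range,
    marker_stats = marker_stats,
    age_building = c(mean = 49.4, sd = 19.1),
    age_longitudinal = c(mean = 40.2, sd = 13.5),
    p_female = c(building = 0.578, longitudinal = 0.553),
    followup_years = 10,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_marker_stats <- function() {
  list(
    building = list(
      scr = c(0.86, 0.17), cys = c(0.83, 0.25), ua = c(5.46, 1.63),
      bun = c(17.5, 5.1), alb = c(4.72, 0.34),
      egfr_ckdepi_cre_2021 = c(95.0, 19.4),
      egfr_ckdepi_cys_2012 = c(100.7, 24.5)
    ),
    longitudinal = list(
      scr = c(0.85, 0.15), cys = c(0.75, 0.13), ua = c(5.18, 1.31),
      bun = c(16.3, 4.1), alb = c(4.76, 0.33),
      egfr_ckdepi_cre_2021 = c(100.8, 16.1),
      egfr_ckdepi_cys_2012 = c(111.3, 15.7)
    )
  )
}

#' @rdname cohort_config
#' @export
default_covariate_effects <- function() {
  list(
    scr = c(age = 0.10, male = 0.40),
    cys = c(age = 0.35, male = 0.05),
    ua  = c(age = 0.10, male = 0.45),
    bun = c(age = 0.30, male = 0.10),
    egfr_ckdepi_cre_2021 = c(age = -0.25, male = 0.00),
    egfr_ckdepi_cys_2012 = c(age = -0.30, male = 0.00)
  )
}

# truncated-normal draw by rejection (bounds are several SDs out, so the
# acceptance rate is high)
.rtnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

.generate_set <- function(cfg, which, n, eta) {
  stats_set <- cfg$marker_stats[[which]]
  agepar <- if (which == "building") cfg$age_building else cfg$age_longitudinal
  pf <- cfg$p_female[[which]]
  female <- stats::runif(n) < pf
  age <- .rtnorm(n, agepar[["mean"]], agepar[["sd"]],
                 cfg$age_range[1], cfg$age_range[2])
  z_age <- (age - agepar[["mean"]]) / agepar[["sd"]]
  z_sex <- (as.numeric(!female) - (1 - pf)) / sqrt(pf * (1 - pf))

  gen_names <- c("scr", "cys", "ua", "bun")
  if (cfg$direct_egfr)
    gen_names <- c(gen_names, "egfr_ckdepi_cre_2021", "egfr_ckdepi_cys_2012")
  cols <- list()
  for (nm in gen_names) {
    lam <- cfg$loadings[[nm]]
    ce <- cfg$covariate_effects[[nm]]
    b_age <- if (is.null(ce)) 0 else ce[["age"]]
    b_sex <- if (is.null(ce)) 0 else ce[["male"]]
    resid_sd <- sqrt(1 - lam^2 - b_age^2 - b_sex^2)
    x <- lam * eta + b_age * z_age + b_sex * z_sex +
      resid_sd * stats::rnorm(n)
    ms <- stats_set[[nm]]
    cols[[nm]] <- ms[1] + ms[2] * x
  }
  # markers are physical quantities: keep them positive (the configured
  # means are > 3 SDs from zero, so clipping is essentially never active)
  for (nm in c("scr", "cys", "ua", "bun"))
    cols[[nm]] <- pmax(cols[[nm]], 0.05 * stats_set[[nm]][1])
  alb <- pmax(stats_set$alb[1] + stats_set$alb[2] * stats::rnorm(n), 1)

  df <- data.frame(
    id = paste0(substr(which, 1, 1), seq_len(n)),
    age = age, sex = ifelse(female, "F", "M"),
    scr = cols$scr, cys = cols$cys, ua = cols$ua, bun = cols$bun,
    alb = alb, eta = eta, stringsAsFactors = FALSE
  )
  df <- egfr_table(df)
  if (cfg$direct_egfr) {
    # overwrite the two model-2 indicator columns with the directly
    # generated versions (documented synthetic mode)
    df$egfr_ckdepi_cre_2021 <- cols$egfr_ckdepi_cre_2021
    df$egfr_ckdepi_cys_2012 <- cols$egfr_ckdepi_cys_2012
  }
  df
}

.generate_followup <- function(cfg, base) {
  n <- nrow(base)
  male <- base$sex == "M"
  fage <- base$age + cfg$followup_years - stats::runif(n, 0, 2)
  fage <- pmin(fage, 95)
  k <- cfg$coupling
  neg_eta <- -base$eta
  sbp <- stats::rnorm(n, 97 + 0.55 * fage + 5 * male + 4 * k * neg_eta, 12)
  sbp <- pmin(pmax(sbp, 85), 230)
  tc <- stats::rnorm(n, 155 + 0.9 * fage + 6 * k * neg_eta, 30)
  tc <- pmax(tc, 90)
  hdl <- stats::rnorm(n, 62 - 0.05 * fage - 8 * male - 3 * k * neg_eta, 12)
  hdl <- pmin(pmax(hdl, 20), tc - 25)
  smoker <- stats::runif(n) < stats::plogis(-1.2 - 0.02 * (fage - 50) + 0.3 * male)
  diabetes <- stats::runif(n) < stats::plogis(-6 + 0.06 * fage + 0.3 * male + 0.5 * k * neg_eta)
  treated <- stats::runif(n) < stats::plogis(-5 + 0.07 * fage + 0.2 * male + 0.4 * k * neg_eta)
  prior_cvd <- stats::runif(n) < stats::plogis(-4.5 + 0.06 * fage + 0.3 * male + 0.3 * k * neg_eta)
  data.frame(
    id = base$id, age = fage, sex = base$sex,
    tc = tc, hdl = hdl, sbp = sbp,
    treated_htn = treated, diabetes = diabetes, smoker = smoker,
    prior_cvd = prior_cvd, stringsAsFactors = FALSE
  )
}

#' Generate a paired synthetic cohort
#'
#' Draws the model-building and longitudinal sets from the configured
#' one-factor generative structure and, for the longitudinal set, the
#' follow-up risk-factor table (~10 years after baseline). Fully
#' deterministic given `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Object of class `"synthetic_cohort"`: list with `building`
#'   (baseline markers + demographics + true `eta` + six eGFR columns),
#'   `longitudinal` (same layout), `followup` (risk factors incl.
#'   `prior_cvd`), and `truth` (the full generative parameter record).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eta_b <- stats::rnorm(config$n_building)
  building <- .generate_set(config, "building", config$n_building, eta_b)
  eta_l <- stats::rnorm(config$n_longitudinal)
  longitudinal <- .generate_set(config, "longitudinal", config$n_longitudinal, eta_l)
  followup <- .generate_followup(config, longitudinal)
  truth <- config
  truth$seed_used <- as.integer(seed)
  out <- list(building = building, longitudinal = longitudinal,
              followup = followup, truth = unclass(truth))
  class(out) <- "synthetic_cohort"
  out
}

#' Population quantities implied by the generative truth
#'
#' Recomputes, from the truth record alone, the implied correlation
#' matrix of the generated indicators (including the covariate-induced
#' part when effects are enabled), the true loadings, and a
#' closed-form population AUC helper for an equal-variance binormal
#' score (`pnorm(delta / sqrt(2))`).
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param indicators Which generated indicator columns to include.
#' @return List with `loadings`, `implied_correlation` (marginal, i.e.
#'   including covariate-induced covariance), `implied_conditional_correlation`
#'   (covariates partialled out), and function `auc_binormal(delta)`.
#' @export
truth_report <- function(cohort,
                         indicators = c("scr", "cys", "ua", "bun")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  lam <- tr$loadings[indicators]
  B <- t(vapply(indicators, function(nm) {
    ce <- tr$covariate_effects[[nm]]
    if (is.null(ce)) c(0, 0) else c(ce[["age"]], ce[["male"]])
  }, numeric(2)))
  # standardized scale: cov = lambda lambda' + B B' + diag(resid)
  Sig <- tcrossprod(lam) + tcrossprod(B)
  diag(Sig) <- 1
  dimnames(Sig) <- list(indicators, indicators)
  Sig_cond <- tcrossprod(lam) + diag(1 - lam^2 - rowSums(B^2))
  # conditional correlation: rescale to unit diagonal
  d <- sqrt(diag(Sig_cond))
  Sig_cond <- Sig_cond / tcrossprod(d)
  dimnames(Sig_cond) <- list(indicators, indicators)
  list(
    loadings = lam,
    covariate_effects = B,
    implied_correlation = Sig,
    implied_conditional_correlation = Sig_cond,
    auc_binormal = function(delta) stats::pnorm(delta / sqrt(2))
  )
}
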