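# End-to-end orchestration: fit the measurement models on the
# model-building set, score the longitudinal set, compute risk outcomes,
# and build the ranked C-statistic comparison.

#' Run configuration for the full analysis
#'
#' @param cohort_config A [cohort_config()] for synthetic generation, or
#'   `NULL` when `paths` point at existing CSV inputs.
#' @param paths Optional named list of CSV paths (`building`,
#'   `longitudinal`, `followup`) read with [read_stamped_csv()].
#' @param models Model ids to fit (default 1:5).
#' @param prediction_models Model ids whose factor scores enter the
#'   prediction comparison. Model 5 is excluded by default; pass
#'   `1:5` to re-include it.
#' @param reference Reference predictor for the DeLong contrasts
#'   (default the model-2 latent score).
#' @param cutoff High-risk cutoff for both risk scores.
#' @param exclude_prior_cvd Drop subjects with prior CVD before scoring
#'   outcomes (default `TRUE`); the dropped count is logged either way.
#' @param score_with Either `"building"` (default: apply the
#'   model-building fit to the longitudinal set, the train/test design)
#'   or `"refit"` (refit each model on the longitudinal set before
#'   scoring).
#' @param seed Master seed; child seeds are derived per stage.
#' @param out_dir Output directory for [run_all()]; `NULL` disables
#'   file output.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(cohort_config = NULL, paths = NULL,
                       models = 1:5, prediction_models = 1:4,
                       reference = "sem_2", cutoff = 0.05,
                       exclude_prior_cvd = TRUE,
                       score_with = c("building", "refit"),
                       seed = 1L, out_dir = NULL) {
  score_with <- match.arg(score_with)
  if (is.null(cohort_config) && is.null(paths))
    stop("either cohort_config or paths must be given", call. = FALSE)
  stopifnot(cutoff > 0, cutoff < 1)
  cfg <- list(cohort_config = cohort_config, paths = paths,
              models = models, prediction_models = prediction_models,
              reference = reference, cutoff = cutoff,
              exclude_prior_cvd = exclude_prior_cvd,
              score_with = score_with,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Fit the measurement models on the model-building set
#'
#' @param building Baseline table with marker and eGFR columns (see
#'   [egfr_table()]) plus `age`, `sex`.
#' @param config A [run_config()].
#' @return List with `fits` (one `"sem_fit"` per model id) and
#'   `summary`: a long data frame of standardized loadings with CFI,
#'   RMSEA, chi-square, df and n per model.
#' @export
run_model_building <- function(building, config) {
  fits <- list()
  rows <- list()
  for (mid in config$models) {
    spec <- sem_model_spec(mid)
    fit <- fit_ml(building, spec)
    fits[[paste0("model_", mid)]] <- fit
    rows[[length(rows) + 1]] <- data.frame(
      model = mid, indicator = fit$indicators,
      loading = unname(fit$loadings),
      std_loading = unname(fit$std_loadings),
      resid_var = unname(fit$psi),
      cfi = fit$cfi, rmsea = fit$rmsea,
      chisq = fit$chisq, df = fit$df, n = fit$n,
      converged = fit$convergence$converged,
      stringsAsFactors = FALSE
    )
  }
  list(fits = fits, summary = do.call(rbind, rows))
}

#' Score the longitudinal set and compare predictors
#'
#' Builds the predictor panel (latent factor scores from the selected
#' models plus the six eGFR columns), computes the 10-year risk
#' outcomes from the follow-up table, dichotomizes them, and evaluates
#' every predictor by univariable logistic regression, C-statistic with
#' DeLong interval, DeLong test against the reference predictor, and
#' explained variance of the log risk scores.
#'
#' @param longitudinal Baseline table of the longitudinal set (markers +
#'   eGFR columns + `age`, `sex`).
#' @param followup Follow-up risk-factor table (matched by `id`).
#' @param fits Fitted models from [run_model_building()].
#' @param config A [run_config()].
#' @return List with `panel` (predictors + risks + outcomes),
#'   `comparison` (named list of ranked comparison tables, one per
#'   outcome), `r2` (explained variance of log-FRS/log-PCE per
#'   predictor), and `log` (row counts at every filter).
#' @export
run_longitudinal <- function(longitudinal, followup, fits, config) {
  log <- list(n_longitudinal = nrow(longitudinal),
              n_followup = nrow(followup))

  # latent scores
  scores <- list()
  for (mid in config$prediction_models) {
    fit <- fits[[paste0("model_", mid)]]
    if (is.null(fit)) stop("no fitted model ", mid, call. = FALSE)
    if (config$score_with == "refit")
      fit <- fit_ml(longitudinal, sem_model_spec(mid))
    scores[[paste0("sem_", mid)]] <- factor_scores(fit, longitudinal)
  }
  egfr_cols <- c("egfr_ckdepi_cre_2009", "egfr_ckdepi_cre_2021",
                 "egfr_ckdepi_cys_2012", "egfr_ckdepi_crecys_2021",
                 "egfr_mdrd4", "egfr_mdrd6")
  panel <- data.frame(id = longitudinal$id, scores,
                      longitudinal[, egfr_cols],
                      stringsAsFactors = FALSE)

  # outcomes from the follow-up table
  fu <- followup[match(panel$id, followup$id), , drop = FALSE]
  if (config$exclude_prior_cvd && "prior_cvd" %in% names(fu)) {
    keep <- !fu$prior_cvd
    log$n_prior_cvd_excluded <- sum(!keep, na.rm = TRUE)
    panel <- panel[keep, , drop = FALSE]
    fu <- fu[keep, , drop = FALSE]
  }
  fu <- risk_table(fu, cutoff = config$cutoff)
  panel$frs_10yr <- fu$frs_10yr
  panel$pce_10yr <- fu$pce_10yr
  panel$frs_high <- as.integer(fu$frs_high)
  panel$pce_high <- as.integer(fu$pce_high)

  pred_cols <- c(names(scores), egfr_cols)
  complete <- stats::complete.cases(panel[, c(pred_cols, "frs_high", "pce_high")])
  log$n_incomplete_dropped <- sum(!complete)
  panel_cc <- panel[complete, , drop = FALSE]
  log$n_scored <- nrow(panel_cc)
  log$n_frs_high <- sum(panel_cc$frs_high)
  log$n_pce_high <- sum(panel_cc$pce_high)

  comparison <- list(
    frs = comparison_report(panel_cc[, pred_cols], panel_cc$frs_high,
                            reference = config$reference),
    pce = comparison_report(panel_cc[, pred_cols], panel_cc$pce_high,
                            reference = config$reference)
  )
  r2 <- data.frame(
    predictor = pred_cols,
    r2_log_frs = vapply(pred_cols, function(p)
      r2_log_outcome(panel_cc[[p]], panel_cc$frs_10yr), 0),
    r2_log_pce = vapply(pred_cols, function(p)
      r2_log_outcome(panel_cc[[p]], panel_cc$pce_10yr), 0),
    stringsAsFactors = FALSE
  )
  rownames(r2) <- NULL
  list(panel = panel_cc, comparison = comparison, r2 = r2, log = log)
}

#' Run the complete analysis
#'
#' Generates (or reads) the two cohort sets, fits the measurement
#' models on the model-building set, scores and evaluates the
#' longitudinal set, and optionally writes all result tables to
#' `config$out_dir`, each stamped with the configuration hash and seed.
#' Re-running with the same configuration and seed reproduces every
#' output byte-for-byte.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `building` (fits + summary),
#'   `longitudinal` (panel, comparisons, r2, log), `hash`, `seed`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])

  if (!is.null(config$cohort_config)) {
    cohort <- generate_cohort(config$cohort_config,
                              seed = child_seed(config$seed, "simulate"))
    building <- cohort$building
    longitudinal <- cohort$longitudinal
    followup <- cohort$followup
  } else {
    building <- egfr_table(read_stamped_csv(config$paths$building))
    longitudinal <- egfr_table(read_stamped_csv(config$paths$longitudinal))
    followup <- read_stamped_csv(config$paths$followup)
    cohort <- NULL
  }

  mb <- run_model_building(building, config)
  lg <- run_longitudinal(longitudinal, followup, mb$fits, config)

  out <- list(cohort = cohort, building = mb, longitudinal = lg,
              hash = hash, seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name)
      write_stamped_csv(df, file.path(config$out_dir, name), hash, config$seed)
    if (!is.null(cohort)) {
      w(cohort$building, "building_markers.csv")
      w(cohort$longitudinal, "longitudinal_markers.csv")
      w(cohort$followup, "followup_risk.csv")
    }
    w(mb$summary, "model_summary.csv")
    w(lg$panel, "predictor_panel.csv")
    w(lg$comparison$frs, "comparison_frs.csv")
    w(lg$comparison$pce, "comparison_pce.csv")
    w(lg$r2, "r2_table.csv")
    summary_json <- list(
      config_hash = hash, seed = config$seed,
      models = lapply(mb$fits, function(f) list(
        cfi = f$cfi, rmsea = f$rmsea, chisq = f$chisq, df = f$df,
        n = f$n, converged = f$convergence$converged
      )),
      counts = lg$log
    )
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
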