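# Discrimination measures: Mann-Whitney AUC, DeLong variance and paired
# test, logistic calibration, explained variance on log risk scores.

.check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both outcome classes must be present", call. = FALSE)
  labels
}

# Placement values of cases and controls (midrank/half-tie convention):
# V10[i] = Pr-hat(case i outranks a random control), V01[j] likewise.
.delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' C-statistic (area under the ROC curve)
#'
#' Mann-Whitney estimator with half credit for ties:
#' `(#concordant + 0.5 #tied) / (#cases * #controls)`, computed via
#' midranks in O(n log n).
#'
#' @param scores Numeric predictor values (higher = more case-like).
#' @param labels Binary outcome, 1 = case; both classes required.
#' @return The AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  .delong_placements(scores, labels)$auc
}

#' DeLong variance of a single AUC
#'
#' Empirical variance of the placement values:
#' `var(V10)/m + var(V01)/n` with sample variances (denominator k-1).
#'
#' @inheritParams auc_mw
#' @return Variance of the AUC estimate.
#' @export
delong_variance <- function(scores, labels) {
  labels <- .check_labels(labels)
  pl <- .delong_placements(scores, labels)
  stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
}

#' Confidence interval for an AUC
#'
#' Wald interval on the AUC scale, `auc +/- z * sqrt(DeLong variance)`,
#' truncated to \[0, 1\]; optionally on the logit scale (back-transformed,
#' never needs truncation).
#'
#' @inheritParams auc_mw
#' @param level Confidence level (default 0.95).
#' @param scale `"auc"` (Wald, default) or `"logit"`.
#' @return List with `auc`, `var`, `lower`, `upper`, `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95, scale = c("auc", "logit")) {
  scale <- match.arg(scale)
  labels <- .check_labels(labels)
  pl <- .delong_placements(scores, labels)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "auc") {
    lo <- max(0, pl$auc - z * sqrt(v))
    hi <- min(1, pl$auc + z * sqrt(v))
  } else {
    a <- min(max(pl$auc, 1e-12), 1 - 1e-12)
    se_logit <- sqrt(v) / (a * (1 - a))
    lg <- log(a / (1 - a))
    lo <- stats::plogis(lg - z * se_logit)
    hi <- stats::plogis(lg + z * se_logit)
  }
  list(auc = pl$auc, var = v, lower = lo, upper = hi, level = level)
}

#' DeLong test for two paired AUCs
#'
#' Compares the C-statistics of two predictors measured on the same
#' subjects with the same outcome, using the covariance of their
#' placement values: `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`
#' with a two-sided normal p-value. Ties get midrank placements.
#'
#' @param scores_a,scores_b Paired predictor vectors.
#' @param labels Binary outcome shared by both predictors.
#' @param level Confidence level for the per-AUC intervals.
#' @return Object of class `"roc_comparison"`: `auc_a`, `auc_b`,
#'   `var_a`, `var_b`, `cov_ab`, `z`, `p`, `ci_a`, `ci_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels, level = 0.95) {
  labels <- .check_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- .delong_placements(scores_a, labels)
  pb <- .delong_placements(scores_b, labels)
  var_a <- stats::var(pa$v10) / pa$m + stats::var(pa$v01) / pa$n
  var_b <- stats::var(pb$v10) / pb$m + stats::var(pb$v01) / pb$n
  cov_ab <- stats::cov(pa$v10, pb$v10) / pa$m + stats::cov(pa$v01, pb$v01) / pa$n
  se2 <- var_a + var_b - 2 * cov_ab
  if (se2 <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(se2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(
    auc_a = pa$auc, auc_b = pb$auc,
    var_a = var_a, var_b = var_b, cov_ab = cov_ab,
    z = z, p = p,
    ci_a = c(max(0, pa$auc - zq * sqrt(var_a)), min(1, pa$auc + zq * sqrt(var_a))),
    ci_b = c(max(0, pb$auc - zq * sqrt(var_b)), min(1, pb$auc + zq * sqrt(var_b))),
    level = level
  )
  class(out) <- "roc_comparison"
  out
}

#' @export
print.roc_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Paired AUC comparison (DeLong)\n  AUC A: %.*f [%.*f, %.*f]\n  AUC B: %.*f [%.*f, %.*f]\n  z = %.3f, two-sided p = %.3g\n",
              digits, x$auc_a, digits, x$ci_a[1], digits, x$ci_a[2],
              digits, x$auc_b, digits, x$ci_b[1], digits, x$ci_b[2],
              x$z, x$p))
  invisible(x)
}

#' Univariable logistic regression of a binary outcome on one predictor
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' (`stats::glm`), returning the fitted probabilities used as the
#' direction-free ROC input. Quasi-perfect separation is flagged and the
#' Wald standard errors suppressed.
#'
#' @param predictor Numeric vector.
#' @param outcome Binary 0/1 vector with both classes present.
#' @return List with `intercept`, `slope`, `se` (named, or `NULL` if
#'   separation), `fitted` probabilities, `separation` flag and the
#'   underlying `glm` object.
#' @export
logistic_fit <- function(predictor, outcome) {
  outcome <- .check_labels(outcome)
  stopifnot(length(predictor) == length(outcome), !anyNA(predictor))
  fit <- suppressWarnings(
    stats::glm(outcome ~ predictor, family = stats::binomial())
  )
  sep <- !fit$converged || any(abs(fit$linear.predictors) > 25)
  co <- stats::coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       se = if (sep) NULL else sqrt(diag(stats::vcov(fit))),
       fitted = as.vector(stats::fitted(fit)),
       separation = sep, glm = fit)
}

#' Variance of a log risk score explained by one predictor
#'
#' Ordinary least-squares R-squared from the univariable regression of
#' `log(risk)` on the predictor (with intercept). Risks are floored at
#' 1e-12 before the log.
#'
#' @param predictor Numeric vector.
#' @param risk Continuous risk probabilities in (0, 1\].
#' @return R-squared in \[0, 1\].
#' @export
r2_log_outcome <- function(predictor, risk) {
  stopifnot(length(predictor) == length(risk))
  y <- log(pmax(risk, 1e-12))
  summary(stats::lm(y ~ predictor))$r.squared
}

#' ROC curve coordinates
#'
#' Specificity/sensitivity pairs at every distinct threshold, for
#' plotting.
#'
#' @inheritParams auc_mw
#' @return Data frame with columns `threshold`, `specificity`,
#'   `sensitivity`.
#' @export
roc_coordinates <- function(scores, labels) {
  labels <- .check_labels(labels)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / m, 0)
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / n, 0)
  data.frame(threshold = thr, specificity = spec, sensitivity = sens)
}

#' Ranked comparison of kidney indexes as risk predictors
#'
#' For each predictor column: fits the univariable logistic model for
#' the binary outcome, computes the C-statistic of the fitted
#' probabilities with its DeLong confidence interval, and the DeLong
#' p-value against a chosen reference predictor. Rows are sorted by
#' descending C-statistic; the reference row is flagged.
#'
#' @param predictors Data frame of numeric predictor columns.
#' @param outcome Binary 0/1 vector.
#' @param reference Name of the reference column for the pairwise tests.
#' @param level Confidence level.
#' @return Data frame with columns `predictor`, `auc`, `ci_lower`,
#'   `ci_upper`, `delong_p_vs_reference` (`NA` for the reference row),
#'   `is_reference`, sorted by descending `auc`.
#' @export
comparison_report <- function(predictors, outcome, reference, level = 0.95) {
  stopifnot(is.data.frame(predictors), reference %in% names(predictors))
  outcome <- .check_labels(outcome)
  probs <- lapply(predictors, function(p) logistic_fit(p, outcome)$fitted)
  ref <- probs[[reference]]
  rows <- lapply(names(probs), function(nm) {
    ci <- auc_ci(probs[[nm]], outcome, level = level)
    p <- if (nm == reference) NA_real_ else delong_test(ref, probs[[nm]], outcome)$p
    data.frame(predictor = nm, auc = ci$auc,
               ci_lower = ci$lower, ci_upper = ci$upper,
               delong_p_vs_reference = p,
               is_reference = nm == reference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  out
}
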