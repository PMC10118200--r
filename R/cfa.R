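# One-factor confirmatory factor analysis by maximum likelihood.
#
# The measurement model is x = lambda * eta + (covariate effects) + e with
# a single latent factor eta, Var(eta) = phi fixed to 1 for
# identification, and diagonal residual covariance Psi. The ML fit
# minimizes the Wishart discrepancy
#   F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p,   Sigma = lambda lambda' + Psi
# over lambda and log(psi) (the log transform keeps residual variances
# positive). Covariate adjustment (age, sex on selected indicators) uses
# the conditional covariance structure: covariate regressions are
# saturated, so they are estimated by per-indicator least squares and the
# factor model is fitted to the residual covariance matrix.

#' Specify one of the five latent kidney-function measurement models
#'
#' Model 1 measures the latent trait with the raw markers (serum
#' creatinine, cystatin C, uric acid, blood urea nitrogen); model 2
#' replaces creatinine and cystatin C with their eGFR transforms
#' (race-free 2021 creatinine eGFR and 2012 cystatin eGFR); models 3 and
#' 4 are models 1 and 2 with every indicator additionally regressed on
#' age and sex; model 5 is model 4 with the age/sex regressions kept
#' only for uric acid and urea nitrogen.
#'
#' @param model_id Integer 1-5.
#' @return An object of class `"sem_model_spec"`: list with `model_id`,
#'   `indicators` (4 column names) and `covariate_on` (which indicators
#'   get age + sex regressions).
#' @export
sem_model_spec <- function(model_id) {
  if (!(length(model_id) == 1 && model_id %in% 1:5))
    stop("model_id must be a single integer in 1..5", call. = FALSE)
  markers <- c("scr", "cys", "ua", "bun")
  egfrs   <- c("egfr_ckdepi_cre_2021", "egfr_ckdepi_cys_2012", "ua", "bun")
  spec <- switch(model_id,
    `1` = list(indicators = markers, covariate_on = character(0)),
    `2` = list(indicators = egfrs,   covariate_on = character(0)),
    `3` = list(indicators = markers, covariate_on = markers),
    `4` = list(indicators = egfrs,   covariate_on = egfrs),
    `5` = list(indicators = egfrs,   covariate_on = c("ua", "bun"))
  )
  spec$model_id <- as.integer(model_id)
  spec$covariates <- if (length(spec$covariate_on)) c("age", "sex") else character(0)
  class(spec) <- "sem_model_spec"
  spec
}

#' @export
print.sem_model_spec <- function(x, ...) {
  cat(sprintf("One-factor measurement model %d\n  indicators: %s\n",
              x$model_id, paste(x$indicators, collapse = ", ")))
  if (length(x$covariate_on))
    cat(sprintf("  age/sex regressions on: %s\n",
                paste(x$covariate_on, collapse = ", ")))
  invisible(x)
}

# Discrepancy and analytic gradient for theta = c(lambda, log psi).
.fml_objective <- function(theta, S, logdetS) {
  p <- nrow(S)
  lambda <- theta[1:p]
  psi <- exp(theta[(p + 1):(2 * p)])
  Sigma <- tcrossprod(lambda) + diag(psi, p)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(.Machine$double.xmax)
  logdet <- 2 * sum(log(diag(R)))
  Sinv <- chol2inv(R)
  logdet + sum(Sinv * S) - logdetS - p
}

# central-difference Jacobian of the analytic gradient (small problems:
# 2p x 2p with p = 4, so this is cheap)
.num_hessian <- function(theta, S, logdetS, h = 1e-6) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    up <- dn <- theta
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    H[, j] <- (.fml_gradient(up, S, logdetS) - .fml_gradient(dn, S, logdetS)) / (2 * h)
  }
  (H + t(H)) / 2
}

.fml_gradient <- function(theta, S, logdetS) {
  p <- nrow(S)
  lambda <- theta[1:p]
  psi <- exp(theta[(p + 1):(2 * p)])
  Sigma <- tcrossprod(lambda) + diag(psi, p)
  Sinv <- chol2inv(chol(Sigma))
  # dF/dSigma = Sigma^-1 (Sigma - S) Sigma^-1
  G <- Sinv %*% (Sigma - S) %*% Sinv
  c(2 * as.vector(G %*% lambda), diag(G) * psi)
}

#' Fit the one-factor model by maximum likelihood
#'
#' Accepts either a per-subject data table (indicator columns plus,
#' for covariate models, `age` and `sex`) or a covariance/correlation
#' matrix with a sample size. Rows with any missing indicator or
#' covariate are listwise-deleted (counts are recorded). The latent
#' variance is fixed to 1; the factor orientation is canonicalized so the
#' first indicator's loading is positive.
#'
#' @param x Data frame, or symmetric positive-definite covariance matrix
#'   whose dimnames match the indicators.
#' @param spec A [sem_model_spec()]; may be `NULL` when `x` is a matrix
#'   (its columns are then taken as the indicators, no covariates).
#' @param n Sample size; required when `x` is a matrix.
#' @param chisq_multiplier `"n-1"` (Wishart convention, default) or
#'   `"n"`: the factor converting the discrepancy to the model chi-square.
#' @param grad_tol Convergence tolerance on the gradient infinity norm.
#' @return Object of class `"sem_fit"`: raw and standardized loadings,
#'   residual variances, covariate coefficient table, discrepancy
#'   `fml`, chi-squares and dfs for model and independence baseline,
#'   `cfi`, `rmsea`, convergence diagnostics, centering means and the
#'   analyzed covariance matrix.
#' @export
fit_ml <- function(x, spec = NULL, n = NULL,
                   chisq_multiplier = c("n-1", "n"), grad_tol = 1e-8) {
  chisq_multiplier <- match.arg(chisq_multiplier)
  covariate_coef <- NULL
  center <- NULL
  n_dropped <- 0L

  if (is.matrix(x)) {
    S <- x
    if (is.null(n)) stop("n is required when fitting to a covariance matrix",
                         call. = FALSE)
    if (!isSymmetric(unname(S))) stop("covariance matrix must be symmetric",
                                      call. = FALSE)
    indicators <- colnames(S)
    if (is.null(indicators)) indicators <- paste0("x", seq_len(nrow(S)))
    if (!is.null(spec)) {
      S <- S[spec$indicators, spec$indicators]
      indicators <- spec$indicators
    }
  } else {
    if (is.null(spec)) stop("spec is required when fitting to raw data",
                            call. = FALSE)
    indicators <- spec$indicators
    needed <- c(indicators, spec$covariates)
    miss <- setdiff(needed, names(x))
    if (length(miss))
      stop("data lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    dat <- x[, needed, drop = FALSE]
    if ("sex" %in% names(dat)) dat$sex <- as.numeric(is_female(dat$sex))
    cc <- stats::complete.cases(dat)
    n_dropped <- sum(!cc)
    dat <- dat[cc, , drop = FALSE]
    n <- nrow(dat)
    if (n <= length(indicators))
      stop("need more complete rows than observed variables", call. = FALSE)
    center <- colMeans(dat[, indicators, drop = FALSE])
    Y <- as.matrix(dat[, indicators, drop = FALSE])
    if (length(spec$covariate_on)) {
      X <- cbind(1, as.matrix(dat[, spec$covariates, drop = FALSE]))
      covariate_coef <- matrix(0, ncol(X), length(indicators),
                               dimnames = list(c("(Intercept)", spec$covariates),
                                               indicators))
      for (ind in spec$covariate_on) {
        b <- stats::lm.fit(X, Y[, ind])$coefficients
        covariate_coef[, ind] <- b
        Y[, ind] <- Y[, ind] - X %*% b
      }
      # untouched indicators keep their mean as intercept
      for (ind in setdiff(indicators, spec$covariate_on))
        covariate_coef["(Intercept)", ind] <- center[[ind]]
    }
    S <- stats::cov(Y)   # denominator n - 1
  }

  p <- nrow(S)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0)
    stop("covariance matrix is not positive definite", call. = FALSE)
  logdetS <- sum(log(ev$values))

  # deterministic start: first principal component direction
  lambda0 <- ev$vectors[, 1] * sqrt(ev$values[1])
  psi0 <- pmax(diag(S) - lambda0^2, 0.05 * diag(S))
  theta0 <- c(lambda0, log(psi0))

  opt <- stats::nlminb(theta0, .fml_objective, gradient = .fml_gradient,
                       S = S, logdetS = logdetS,
                       control = list(iter.max = 1000, eval.max = 2000,
                                      rel.tol = 1e-15, x.tol = 1e-15))
  # polish: Newton steps on the analytic gradient (finite-difference
  # Hessian) until the gradient infinity norm meets the tolerance
  theta <- opt$par
  fcur <- .fml_objective(theta, S, logdetS)
  for (it in 1:25) {
    g <- .fml_gradient(theta, S, logdetS)
    if (max(abs(g)) < grad_tol / 10) break
    H <- .num_hessian(theta, S, logdetS)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    accepted <- FALSE
    for (s in c(1, 0.5, 0.25, 0.1, 0.01)) {
      cand <- theta - s * step
      fcand <- .fml_objective(cand, S, logdetS)
      if (is.finite(fcand) && fcand <= fcur + 1e-12) {
        theta <- cand; fcur <- fcand; accepted <- TRUE; break
      }
    }
    if (!accepted) break
  }
  opt$par <- theta
  fml <- max(fcur, 0)   # the discrepancy is non-negative; clamp rounding
  grad <- .fml_gradient(opt$par, S, logdetS)
  grad_norm <- max(abs(grad))

  lambda <- opt$par[1:p]
  psi <- exp(opt$par[(p + 1):(2 * p)])
  if (lambda[1] < 0) lambda <- -lambda   # sign canonicalization
  names(lambda) <- names(psi) <- indicators

  heywood <- psi < 1e-6 * diag(S)
  if (any(heywood)) {
    warning("Heywood case: residual variance at the zero bound for ",
            paste(indicators[heywood], collapse = ", "), call. = FALSE)
    psi[heywood] <- pmax(psi[heywood], 1e-8 * diag(S)[heywood])
  }

  Sigma <- tcrossprod(lambda) + diag(psi, p)
  std_loadings <- lambda / sqrt(diag(Sigma))
  names(std_loadings) <- indicators

  mult <- if (chisq_multiplier == "n-1") n - 1 else n
  df_m <- p * (p + 1) / 2 - 2 * p
  chisq_m <- mult * fml
  fml_b <- sum(log(diag(S))) - logdetS   # independence baseline
  chisq_b <- mult * fml_b
  df_b <- p * (p - 1) / 2

  fit <- list(
    spec = spec, indicators = indicators,
    loadings = lambda, psi = psi, phi = 1,
    std_loadings = std_loadings,
    covariate_coef = covariate_coef, center = center,
    S = S, n = n, n_dropped = n_dropped,
    fml = fml, chisq = chisq_m, df = df_m,
    baseline_chisq = chisq_b, baseline_df = df_b,
    chisq_multiplier = chisq_multiplier,
    convergence = list(code = opt$convergence, grad_norm = grad_norm,
                       converged = grad_norm < grad_tol,
                       heywood = any(heywood))
  )
  idx <- fit_indices_(chisq_m, df_m, chisq_b, df_b, n)
  fit$cfi <- idx[["cfi"]]
  fit$rmsea <- idx[["rmsea"]]
  class(fit) <- "sem_fit"
  fit
}

fit_indices_ <- function(chisq_m, df_m, chisq_b, df_b, n) {
  num <- max(chisq_m - df_m, 0)
  den <- max(chisq_b - df_b, chisq_m - df_m, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- if (df_m > 0) sqrt(max(chisq_m - df_m, 0) / (df_m * (n - 1))) else 0
  c(cfi = cfi, rmsea = rmsea)
}

#' Comparative fit index and RMSEA of a fitted model
#'
#' CFI compares the model chi-square to the independence baseline:
#' `1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b, chisq_m - df_m, 0)`.
#' RMSEA is `sqrt(max(chisq_m - df_m, 0) / (df_m * (n - 1)))`.
#'
#' @param fit A `"sem_fit"` object.
#' @return Named numeric vector `c(cfi = , rmsea = )`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  fit_indices_(fit$chisq, fit$df, fit$baseline_chisq, fit$baseline_df, fit$n)
}

#' Standardized loadings of a fitted model
#'
#' Standardizes each raw loading by the model-implied indicator standard
#' deviation (`lambda_i * sd(eta) / sd(x_i)`); with unit latent variance
#' the squared standardized loading plus the standardized residual
#' variance equals 1 per indicator. For covariate models the scale is the
#' conditional (age/sex-partialled) indicator variance.
#'
#' @param fit A `"sem_fit"` object.
#' @return Named numeric vector of standardized loadings in \[-1, 1\].
#' @export
standardized_loadings <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  fit$std_loadings
}

#' Per-subject latent factor scores
#'
#' Regression-method scores `f = phi * lambda' Sigma^-1 (x - mu)`, with
#' age/sex effects partialled out first for covariate models, using the
#' regression coefficients and centering means stored in the fit (so a
#' model estimated on one set can score another). The sign follows the
#' fit's canonicalization: scores correlate positively with the first
#' indicator.
#'
#' @param fit A `"sem_fit"` object estimated from raw data (it must carry
#'   centering means), or from a covariance matrix if `center` is given.
#' @param data Data frame with the indicator (and covariate) columns.
#' @param center Optional named means overriding those stored in the fit.
#' @return Numeric vector with one score per row of `data`; `NA` for rows
#'   with missing inputs. Attribute `method` = `"regression"`.
#' @export
factor_scores <- function(fit, data, center = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  indicators <- fit$indicators
  if (is.null(center)) center <- fit$center
  if (is.null(center))
    stop("fit carries no centering means; supply `center`", call. = FALSE)
  needed <- indicators
  covs <- if (!is.null(fit$spec)) fit$spec$covariates else character(0)
  if (length(covs)) needed <- c(needed, covs)
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("data lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  Y <- as.matrix(data[, indicators, drop = FALSE])
  complete <- stats::complete.cases(data[, needed, drop = FALSE])
  if (!is.null(fit$covariate_coef)) {
    dat <- data
    dat$sex <- as.numeric(is_female(dat$sex))
    X <- cbind(1, as.matrix(dat[, covs, drop = FALSE]))
    adjusted <- fit$spec$covariate_on
    Y[, adjusted] <- Y[, adjusted] -
      X %*% fit$covariate_coef[, adjusted, drop = FALSE]
    plain <- setdiff(indicators, adjusted)
    if (length(plain))
      Y[, plain] <- sweep(Y[, plain, drop = FALSE], 2, center[plain])
  } else {
    Y <- sweep(Y, 2, center[indicators])
  }
  Sigma <- tcrossprod(fit$loadings) + diag(fit$psi, length(indicators))
  w <- fit$phi * solve(Sigma, fit$loadings)
  scores <- as.vector(Y %*% w)
  scores[!complete] <- NA_real_
  attr(scores, "method") <- "regression"
  scores
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("One-factor ML fit (n = %d%s)\n", x$n,
              if (x$n_dropped) sprintf(", %d incomplete rows dropped", x$n_dropped) else ""))
  tab <- data.frame(loading = x$loadings, std_loading = x$std_loadings,
                    resid_var = x$psi)
  print(round(tab, digits))
  cat(sprintf("F_ML = %.3g, chisq(%d) = %.3f, CFI = %.3f, RMSEA = %.3f\n",
              x$fml, x$df, x$chisq, x$cfi, x$rmsea))
  if (!x$convergence$converged)
    cat(sprintf("WARNING: not converged (gradient inf-norm %.2e)\n",
                x$convergence$grad_norm))
  invisible(x)
}

#' Implied covariance matrix of a one-factor parameter vector
#'
#' `Sigma = phi * lambda lambda' + diag(psi)`. With standardized loadings
#' and `psi = 1 - lambda^2` this is the implied correlation matrix used
#' by the analytic recovery checks.
#'
#' @param loadings Numeric loading vector.
#' @param psi Residual variances; default `1 - loadings^2`.
#' @param phi Latent variance (default 1).
#' @return Symmetric matrix with the loadings' names as dimnames.
#' @export
implied_covariance <- function(loadings, psi = 1 - loadings^2, phi = 1) {
  if (any(psi < 0)) stop("residual variances must be non-negative", call. = FALSE)
  Sigma <- phi * tcrossprod(loadings) + diag(psi, length(loadings))
  if (!is.null(names(loadings)))
    dimnames(Sigma) <- list(names(loadings), names(loadings))
  Sigma
}
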