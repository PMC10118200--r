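test_that("the five model specifications have the documented structure", {
  m1 <- sem_model_spec(1)
  expect_equal(m1$indicators, c("scr", "cys", "ua", "bun"))
  expect_length(m1$covariate_on, 0)
  m2 <- sem_model_spec(2)
  expect_equal(m2$indicators,
               c("egfr_ckdepi_cre_2021", "egfr_ckdepi_cys_2012", "ua", "bun"))
  expect_length(m2$covariate_on, 0)
  m3 <- sem_model_spec(3)
  expect_equal(m3$covariate_on, m3$indicators)
  m4 <- sem_model_spec(4)
  expect_equal(m4$covariate_on, m4$indicators)
  m5 <- sem_model_spec(5)
  expect_equal(m5$covariate_on, c("ua", "bun"))
  expect_equal(m5$indicators, m4$indicators)
  expect_error(sem_model_spec(7), "1..5")
  expect_error(sem_model_spec(0), "1..5")
})

test_that("fitting the exact implied correlation of an equal-loading model is a zero-discrepancy fixed point", {
  lam <- rep(0.8, 4)
  S <- implied_covariance(lam)
  colnames(S) <- rownames(S) <- paste0("x", 1:4)
  fit <- fit_ml(S, n = 500)
  expect_equal(unname(fit$std_loadings), rep(0.8, 4), tolerance = 1e-7)
  expect_lt(fit$fml, 1e-10)
  expect_equal(fit$df, 2)
  expect_true(fit$convergence$converged)
})

test_that("a diagonal covariance is fitted exactly with no implied cross-correlation", {
  # for uncorrelated indicators the independence model is saturated, so
  # model and baseline chi-squares both vanish; the factor solution is
  # not unique (any single-spike loading vector also has zero
  # discrepancy) but its implied covariance must stay diagonal
  S <- diag(c(1, 2, 0.5, 1.3))
  colnames(S) <- rownames(S) <- paste0("x", 1:4)
  fit <- fit_ml(S, n = 200)
  implied <- implied_covariance(fit$loadings, fit$psi)
  expect_lt(max(abs(implied[upper.tri(implied)])), 1e-5)
  expect_lt(fit$chisq, 1e-6)
  expect_lt(fit$baseline_chisq, 1e-10)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
})

test_that("zero-discrepancy recovery holds for random admissible parameter vectors", {
  set.seed(42)
  for (rep in 1:25) {
    lam <- random_loadings()
    fit <- fit_ml(implied_covariance(lam), n = 1000)
    expect_lt(fit$fml, 1e-8)
    expect_lt(max(abs(fit$loadings - lam)), 1e-4)
  }
})

test_that("flipping the generating sign leaves fit statistics and canonical output unchanged", {
  set.seed(7)
  lam <- random_loadings()
  f1 <- fit_ml(implied_covariance(lam), n = 300)
  f2 <- fit_ml(implied_covariance(-lam), n = 300)
  expect_equal(f1$fml, f2$fml, tolerance = 1e-10)
  expect_equal(f1$cfi, f2$cfi)
  expect_equal(f1$rmsea, f2$rmsea)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-6)
  expect_gt(f1$loadings[1], 0)
})

test_that("squared standardized loading plus standardized residual variance is one", {
  set.seed(99)
  cc <- generate_cohort(quick_config(n_building = 400), seed = 5)
  fit <- fit_ml(cc$building, sem_model_spec(1))
  implied_var <- fit$loadings^2 + fit$psi
  expect_equal(unname(fit$std_loadings^2 + fit$psi / implied_var),
               rep(1, 4), tolerance = 1e-10)
  # already-standardized input: loadings are their own standardization
  lam <- c(a = 0.7, b = 0.6, c = -0.5, d = 0.4)
  f <- fit_ml(implied_covariance(lam), n = 500)
  expect_equal(standardized_loadings(f), f$loadings, tolerance = 1e-6)
  expect_true(all(abs(standardized_loadings(f)) <= 1))
})

test_that("fit indices follow the documented formulas on a fixed chi-square triple", {
  idx <- kidneylatent:::fit_indices_(chisq_m = 20, df_m = 2,
                                     chisq_b = 300, df_b = 6, n = 101)
  expect_equal(idx[["cfi"]], 1 - 18 / 294)
  expect_equal(idx[["rmsea"]], sqrt(18 / (2 * 100)))
  # boundary: model chi-square below its df
  idx0 <- kidneylatent:::fit_indices_(1.5, 2, 300, 6, 101)
  expect_equal(idx0[["cfi"]], 1)
  expect_equal(idx0[["rmsea"]], 0)
  # model no better than the baseline
  idxb <- kidneylatent:::fit_indices_(300, 6, 300, 6, 101)
  expect_equal(idxb[["cfi"]], 0)
})

test_that("the chi-square multiplier switch rescales by n/(n-1)", {
  set.seed(3)
  cc <- generate_cohort(quick_config(n_building = 300), seed = 3)
  f1 <- fit_ml(cc$building, sem_model_spec(1))
  f2 <- fit_ml(cc$building, sem_model_spec(1), chisq_multiplier = "n")
  expect_equal(f2$chisq, f1$chisq * f1$n / (f1$n - 1), tolerance = 1e-10)
})

test_that("degrees of freedom follow the moment count", {
  lam <- c(a = 0.8, b = 0.7, c = 0.6, d = 0.5)
  f <- fit_ml(implied_covariance(lam), n = 100)
  p <- 4
  expect_equal(f$df, p * (p + 1) / 2 - 2 * p)
  expect_equal(f$baseline_df, p * (p - 1) / 2)
})

test_that("a residual variance at the zero bound is flagged as a Heywood case", {
  lam <- c(a = 0.999, b = 0.6, c = 0.5, d = 0.4)
  S <- implied_covariance(lam, psi = pmax(1 - lam^2, 0))
  S[1, 1] <- lam[1]^2 + 1e-7   # first indicator almost fully explained
  expect_warning(fit <- fit_ml(S, n = 500), "Heywood")
  expect_true(fit$convergence$heywood)
  expect_true(all(fit$psi > 0))
})

test_that("regression factor scores are zero at the mean, track the truth, and keep the documented sign", {
  cfg <- cohort_config(n_building = 20000, n_longitudinal = 50,
                       covariate_effects = NULL, direct_egfr = TRUE,
                       loadings = c(scr = -0.757, cys = -0.597,
                                    ua = -0.393, bun = -0.561,
                                    egfr_ckdepi_cre_2021 = 0.889,
                                    egfr_ckdepi_cys_2012 = 0.856))
  cc <- generate_cohort(cfg, seed = 21)
  fit <- fit_ml(cc$building, sem_model_spec(2))
  sc <- factor_scores(fit, cc$building)
  # mean row scores to zero
  mrow <- as.data.frame(as.list(fit$center))
  expect_equal(as.vector(factor_scores(fit, mrow)), 0, tolerance = 1e-10)
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  # sign convention: positive correlation with the first indicator
  expect_gt(cor(sc, cc$building$egfr_ckdepi_cre_2021), 0)
  # correlation with the true latent reaches the closed-form regression
  # score reliability implied by the generating loadings
  lam <- c(0.889, 0.856, -0.393, -0.561)
  Sig <- tcrossprod(lam) + diag(1 - lam^2)
  max_rel <- sqrt(drop(t(lam) %*% solve(Sig) %*% lam))
  expect_gt(cor(sc, cc$building$eta), max_rel - 0.02)
  expect_equal(attr(sc, "method"), "regression")
})

test_that("covariate models partial age and sex out of the scored indicators", {
  cc <- generate_cohort(cohort_config(n_building = 4000, n_longitudinal = 400),
                        seed = 31)
  fit <- fit_ml(cc$building, sem_model_spec(3))
  expect_true(fit$convergence$converged)
  expect_equal(dim(fit$covariate_coef), c(3L, 4L))
  sc_new <- factor_scores(fit, cc$longitudinal)
  expect_true(all(is.finite(sc_new)))
  # scoring another set reuses the stored regression coefficients:
  # scores must still correlate with the latent truth there
  expect_gt(abs(cor(sc_new, cc$longitudinal$eta)), 0.5)
})

test_that("incomplete rows are listwise-deleted with a logged count", {
  cc <- generate_cohort(quick_config(), seed = 8)
  d <- cc$building
  d$scr[1:5] <- NA
  fit <- fit_ml(d, sem_model_spec(1))
  expect_equal(fit$n_dropped, 5L)
  expect_equal(fit$n, nrow(d) - 5L)
  sc <- factor_scores(fit, d)
  expect_true(all(is.na(sc[1:5])))
  expect_true(all(is.finite(sc[-(1:5)])))
})

test_that("covariance-matrix input demands a sample size and positive definiteness", {
  S <- implied_covariance(c(a = 0.8, b = 0.7, c = 0.6, d = 0.5))
  expect_error(fit_ml(S), "n is required")
  bad <- matrix(1, 4, 4)
  colnames(bad) <- rownames(bad) <- letters[1:4]
  expect_error(fit_ml(bad, n = 100), "positive definite")
})
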