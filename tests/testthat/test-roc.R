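test_that("the C-statistic equals hand-counted values on small instances", {
  expect_equal(auc_mw(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_mw(1:10, rep(c(0, 1), each = 5)), 1)          # perfect ranking
  expect_equal(auc_mw(rep(2, 10), rep(c(0, 1), 5)), 0.5)         # all tied
  expect_equal(auc_mw(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)      # one tie
})

test_that("the midrank C-statistic equals brute-force pair counting on random tied instances", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_identical(auc_mw(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("self- and monotone-transform comparisons are exact nulls", {
  set.seed(2)
  s <- rnorm(100)
  y <- rbinom(100, 1, plogis(s))
  r <- delong_test(s, s, y)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  r2 <- delong_test(s, exp(2 * s) + 5, y)   # strictly increasing transform
  expect_equal(r2$z, 0)
  expect_equal(r2$p, 1)
})

test_that("the paired comparison is symmetric up to the sign of z", {
  set.seed(5)
  a <- rnorm(120); b <- rnorm(120)
  y <- rbinom(120, 1, plogis(a + 0.5 * b))
  r_ab <- delong_test(a, b, y)
  r_ba <- delong_test(b, a, y)
  expect_equal(r_ab$z, -r_ba$z)
  expect_equal(r_ab$p, r_ba$p)
  expect_equal(r_ab$cov_ab, r_ba$cov_ab)
})

test_that("AUC, variance, CI and paired p agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  n <- 80
  a <- round(rnorm(n), 1)            # rounded -> ties
  b <- a + rnorm(n)
  y <- rbinom(n, 1, plogis(a))
  roc_a <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  roc_b <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  expect_equal(auc_mw(a, y), as.numeric(pROC::auc(roc_a)))
  expect_equal(delong_variance(a, y), as.numeric(pROC::var(roc_a)))
  ci <- auc_ci(a, y)
  proc_ci <- as.numeric(pROC::ci.auc(roc_a, method = "delong"))
  expect_equal(c(ci$lower, ci$upper), proc_ci[c(1, 3)], tolerance = 1e-10)
  ours <- delong_test(a, b, y)
  theirs <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  expect_equal(ours$p, theirs$p.value, tolerance = 1e-10)
})

test_that("the DeLong p agrees with a paired bootstrap of the AUC difference", {
  set.seed(77)
  n <- 20
  a <- rnorm(n); b <- a * 0.3 + rnorm(n)
  y <- rep(c(0, 1), each = 10)
  d0 <- auc_mw(a, y) - auc_mw(b, y)
  boots <- replicate(20000, {
    idx <- sample(n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample(n, replace = TRUE)
    auc_mw(a[idx], y[idx]) - auc_mw(b[idx], y[idx])
  })
  p_boot <- 2 * pnorm(-abs(d0 / sd(boots)))
  r <- delong_test(a, b, y)
  expect_lt(abs(r$p - p_boot), 0.06)
  expect_lt(abs(sqrt(r$var_a + r$var_b - 2 * r$cov_ab) - sd(boots)) / sd(boots), 0.35)
})

test_that("confidence intervals behave at the boundaries and shrink with n", {
  expect_error(auc_ci(1:5, rep(1, 5)), "both outcome classes")
  set.seed(4)
  widths <- vapply(c(100, 400, 1600), function(n) {
    s <- rnorm(n); y <- rbinom(n, 1, plogis(s))
    ci <- auc_ci(s, y)
    ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
  # symmetric before truncation, truncated into [0,1] after
  s <- c(1:20); y <- c(rep(0, 10), rep(1, 10))
  ci <- auc_ci(s, y)
  expect_lte(ci$upper, 1)
  cil <- auc_ci(s, y, scale = "logit")
  expect_true(cil$lower > 0 && cil$upper < 1)
})

test_that("logistic_fit matches a direct likelihood optimisation and flags separation", {
  x <- c(-1.2, -0.7, -0.3, 0.1, 0.4, 0.9, 1.3, 2.0)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- logistic_fit(x, y)
  nll <- function(b) -sum(y * (b[1] + b[2] * x) - log(1 + exp(b[1] + b[2] * x)))
  ref <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(c(fit$intercept, fit$slope), ref$par, tolerance = 1e-5)
  expect_false(fit$separation)
  # null predictor: slope near zero
  set.seed(6)
  x0 <- rnorm(400); y0 <- rbinom(400, 1, 0.5)
  expect_lt(abs(logistic_fit(x0, y0)$slope), 0.25)
  # perfect separation flagged, standard errors suppressed
  xs <- c(-(5:1), 1:5); ys <- rep(c(0, 1), each = 5)
  sepfit <- logistic_fit(xs, ys)
  expect_true(sepfit$separation)
  expect_null(sepfit$se)
})

test_that("fitted-probability ROC is invariant to monotone predictor transforms", {
  set.seed(8)
  x <- rnorm(150); y <- rbinom(150, 1, plogis(1.2 * x))
  p1 <- logistic_fit(x, y)$fitted
  p2 <- logistic_fit(exp(x), y)$fitted       # monotone but nonlinear
  expect_equal(auc_mw(p1, y), auc_mw(rank(p1), y))   # rank invariance
  expect_equal(auc_mw(x, y), auc_mw(p1, y))          # increasing fit keeps order
  expect_gt(auc_mw(p2, y), 0.5)
})

test_that("explained variance of the log score equals the squared correlation", {
  set.seed(10)
  x <- rnorm(10)
  risk <- plogis(-2 + 0.8 * x + rnorm(10, 0, 0.3))
  expect_equal(r2_log_outcome(x, risk), cor(x, log(risk))^2)
  expect_equal(suppressWarnings(r2_log_outcome(x, exp(2 * x - 5))), 1)  # exact in log
  y_ind <- plogis(rnorm(1000) - 3)
  expect_lt(r2_log_outcome(rnorm(1000), y_ind), 0.02)
})

test_that("the comparison report ranks by descending AUC with the reference flagged", {
  set.seed(12)
  n <- 300
  eta <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * eta))
  preds <- data.frame(strong = eta + rnorm(n, 0, 0.3),
                      weak = eta + rnorm(n, 0, 2),
                      noise = rnorm(n),
                      inverted = -(eta + rnorm(n, 0, 0.3)))
  rep <- comparison_report(preds, y, reference = "strong")
  expect_equal(rep$auc, sort(rep$auc, decreasing = TRUE))
  expect_true(rep$is_reference[rep$predictor == "strong"])
  expect_true(is.na(rep$delong_p_vs_reference[rep$predictor == "strong"]))
  expect_true(all(rep$auc >= 0.5))     # direction-free via fitted probabilities
  expect_lt(rep$delong_p_vs_reference[rep$predictor == "noise"], 1e-6)
  # an inverted copy of the reference discriminates equally well
  expect_gt(rep$auc[rep$predictor == "inverted"], 0.7)
})

test_that("roc_coordinates spans (0,0) to (1,1) and matches the AUC by trapezoid", {
  set.seed(13)
  s <- rnorm(60); y <- rbinom(60, 1, plogis(s))
  co <- roc_coordinates(s, y)
  expect_equal(co$sensitivity[1], 1)
  expect_equal(co$specificity[1], 0)
  expect_equal(co$sensitivity[nrow(co)], 0)
  expect_equal(co$specificity[nrow(co)], 1)
  fpr <- 1 - co$specificity
  trap <- -sum(diff(fpr) * (head(co$sensitivity, -1) + tail(co$sensitivity, -1)) / 2)
  expect_equal(trap, auc_mw(s, y), tolerance = 1e-10)
})
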