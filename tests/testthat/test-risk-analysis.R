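# Risk curves (logistic, censored Weibull), ROC analysis and scoring.

test_that("logistic fit recovers the symmetric midpoint and MLE coefficients", {
  fit <- fit_blr(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(threshold_50(fit), 2.5, tolerance = 1e-6)

  # fixed 20-point overlapping fixture (finite MLE)
  x_neg <- c(1.2, 2.3, 2.8, 3.1, 3.9, 4.4, 4.9, 5.3, 6.1, 7.2)
  x_pos <- c(3.0, 3.7, 4.2, 5.0, 5.5, 6.0, 6.6, 7.0, 8.1, 9.3)
  fx <- list(x = c(x_neg, x_pos), y = rep(c(0L, 1L), each = 10))
  fit <- fit_blr(fx$x, fx$y)
  oracle <- logistic_mle_nr(fx$x, fx$y)
  expect_equal(fit$a, unname(oracle["a"]), tolerance = 1e-6)
  expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-6)
  expect_false(fit$separable)

  # label swap flips the slope but keeps the 50% threshold
  fit_sw <- fit_blr(fx$x, 1 - fx$y)
  expect_equal(fit_sw$b, -fit$b, tolerance = 1e-6)
  expect_equal(threshold_50(fit_sw), threshold_50(fit), tolerance = 1e-6)
})

test_that("separable data are flagged with capped, threshold-preserving slope", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  fit <- fit_blr(x, y)
  expect_true(fit$separable)
  expect_lte(abs(fit$b), 50 / diff(range(x)) + 1e-9)
  th <- threshold_50(fit)
  expect_gt(th, 0.2)
  expect_lt(th, 0.8)
})

test_that("logistic probabilities behave as the closed form dictates", {
  expect_equal(blr_probability(0, a = 0, b = 1), 0.5)
  expect_equal(blr_probability(2.5, a = -5, b = 2), 0.5)
  expect_gt(blr_probability(100, a = -5, b = 2), 1 - 1e-10)
  fit <- fit_blr(c(1, 2, 3, 4, 5), c(0, 0, 1, 0, 1))
  # the 50% threshold is the root of P(x) = 0.5
  root <- uniroot(function(x) blr_probability(x, fit) - 0.5, c(-100, 100),
                  tol = 1e-12)$root
  expect_equal(threshold_50(fit), root, tolerance = 1e-10)
})

test_that("censored Weibull MLE recovers generating parameters", {
  # tolerance T ~ Weibull(5, 3); injured iff T <= exposure x; average the
  # MLE over replicate cohorts to sit below the estimator's sampling spread
  est <- replicate_weibull_fit(n = 2000, alpha = 5, beta = 3, reps = 5, seed = 7)
  expect_lt(abs(est[1] - 5) / 5, 0.05)
  expect_lt(abs(est[2] - 3) / 3, 0.05)

  set.seed(7)
  x <- runif(500, 1, 9)
  y <- as.integer(rweibull(500, 3, 5) <= x)
  fit <- fit_weibull(x, y)
  expect_true(fit$converged)

  # closed-form property: P(alpha) = 1 - exp(-1) for any fit
  expect_equal(weibull_probability(fit$alpha, fit), 1 - exp(-1))
  expect_equal(weibull_probability(-1, fit), 0)
  expect_equal(weibull_probability(0, fit), 0)
  xs <- seq(0.01, 10, 0.01)
  expect_true(all(diff(weibull_probability(xs, fit)) > 0))
})

test_that("the in-package censored likelihood matches survreg", {
  set.seed(9)
  n <- 300
  x <- runif(n, 0.5, 12)
  y <- as.integer(rweibull(n, 3, 5) <= x)
  fit <- fit_weibull(x, y)
  # interval2 coding: injured = left-censored, non-injured = right-censored
  tL <- ifelse(y == 1, NA, x)
  tR <- ifelse(y == 1, x, NA)
  sr <- survival::survreg(survival::Surv(tL, tR, type = "interval2") ~ 1,
                          dist = "weibull")
  expect_equal(fit$alpha, unname(exp(coef(sr))), tolerance = 1e-3)
  expect_equal(fit$beta, 1 / sr$scale, tolerance = 1e-3)
})

test_that("50% thresholds follow the closed forms", {
  expect_equal(threshold_50(structure(list(a = -5, b = 2), class = "risk_fit_blr")),
               2.5)
  wb <- structure(list(alpha = 2, beta = 1), class = "risk_fit_weibull")
  expect_equal(threshold_50(wb), 2 * log(2))
  wb_steep <- structure(list(alpha = 2, beta = 500), class = "risk_fit_weibull")
  expect_equal(threshold_50(wb_steep), 2, tolerance = 1e-2)
  expect_error(threshold_50(structure(list(a = 1, b = 0), class = "risk_fit_blr")),
               "undefined")
})

test_that("AUROC equals pairwise concordance and flips under negation", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  expect_equal(roc_curve(x, y)$auroc, 1)

  for (s in 1:25) {
    fx <- make_fixture(sample(2:6, 1), sample(2:6, 1), shift = runif(1, 0, 2),
                       seed = 100 + s)
    auc <- roc_curve(fx$x, fx$y)$auroc
    expect_equal(auc, concordance_auroc(fx$x, fx$y), tolerance = 1e-12)
    expect_equal(roc_curve(-fx$x, fx$y)$auroc, 1 - auc, tolerance = 1e-12)
  }
  # ties contribute one half
  expect_equal(roc_curve(c(1, 1, 1, 1), c(0, 1, 0, 1))$auroc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both")
})

test_that("optimal ROC threshold matches exhaustive minimization", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  roc <- roc_curve(x, y)
  expect_equal(optimal_roc_threshold(roc), 0.5)

  for (s in 1:20) {
    fx <- make_fixture(4, 4, shift = runif(1, 0.5, 2), seed = 200 + s)
    got <- optimal_roc_threshold(roc_curve(fx$x, fx$y))
    expect_equal(got, brute_force_roc_threshold(fx$x, fx$y), tolerance = 1e-12)
    # optimum distance is zero iff the classes separate perfectly
    sc <- classify_and_score(fx$x, fx$y, got)
    d <- sqrt((1 - sc$SP)^2 + (1 - sc$S)^2)
    separated <- max(fx$x[fx$y == 0]) < min(fx$x[fx$y == 1])
    expect_equal(d == 0, separated)
  }
})

test_that("classification scores implement S, SP and PAR exactly", {
  # at threshold 3.5: TP = 3 of P = 4, TN = 2 of N = 3
  x <- c(1, 2, 3, 10, 11, 12, 4)
  y <- c(0, 0, 1, 1, 1, 1, 0)
  sc <- classify_and_score(x, y, threshold = 3.5)
  expect_equal(c(sc$TP, sc$TN, sc$P, sc$N), c(3, 2, 4, 3))
  expect_equal(sc$S, 0.75)
  expect_equal(sc$SP, 2 / 3)
  expect_equal(sc$PAR, 5 / 7)

  all_right <- classify_and_score(c(1, 2, 8, 9), c(0, 0, 1, 1), 5)
  expect_equal(c(all_right$S, all_right$SP, all_right$PAR), c(1, 1, 1))

  low <- classify_and_score(c(1, 2, 8, 9), c(0, 0, 1, 1), 0)
  expect_equal(c(low$S, low$SP), c(1, 0))

  # ties at the threshold count as negative
  tie <- classify_and_score(c(1, 2), c(1, 0), threshold = 1)
  expect_equal(tie$TP, 0)
})

test_that("PAR is the prevalence-weighted convex combination of S and SP", {
  for (s in 1:20) {
    fx <- make_fixture(sample(3:8, 1), sample(3:8, 1), runif(1, 0, 2),
                       seed = 300 + s)
    th <- median(fx$x)
    sc <- classify_and_score(fx$x, fx$y, th)
    expect_equal(sc$PAR,
                 sc$S * sc$P / (sc$P + sc$N) + sc$SP * sc$N / (sc$P + sc$N),
                 tolerance = 1e-12)
  }
})
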