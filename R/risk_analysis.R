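# Injury risk curves and classification scoring: binary logistic regression,
# censored Weibull survival fits, empirical ROC curves, 50%-risk and
# optimal-ROC thresholds, and sensitivity/specificity/accuracy scoring.

.check_two_classes <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both injured and non-injured cases are required", call. = FALSE)
  }
  y
}

#' Binary logistic regression risk fit
#'
#' Maximum-likelihood fit of the logistic risk curve
#' `P(x) = exp(a + b x) / (1 + exp(a + b x))` to binary injury labels.
#' The quality of fit is summarized by a sum-of-squares R-squared on the
#' 0/1 outcomes, adjusted by `(n - 1)/(n - 2)`. Separable data are flagged
#' and the slope capped at `50 / range(x)` (the 50%-risk threshold is
#' preserved) rather than left diverging.
#'
#' @param x Metric values.
#' @param y Binary labels (1 = injured).
#' @return A list of class `risk_fit_blr` with `a`, `b`, `r2_adj`, `loglik`,
#'   `converged`, `separable`.
#' @export
fit_blr <- function(x, y) {
  y <- .check_two_classes(y)
  stopifnot(length(x) == length(y), all(is.finite(x)))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  separable <- FALSE
  rng <- diff(range(x))
  b_cap <- if (rng > 0) 50 / rng else 50
  if (!is.finite(b) || abs(b) > b_cap) {
    separable <- TRUE
    th <- if (is.finite(b) && b != 0) -a / b else mean(range(x))
    b <- sign(if (is.finite(b) && b != 0) b else 1) * b_cap
    a <- -b * th
  }
  p <- stats::plogis(a + b * x)
  eps <- 1e-12
  loglik <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  n <- length(y)
  r2 <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
  structure(
    list(a = a, b = b, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
         loglik = loglik, converged = fit$converged, separable = separable),
    class = "risk_fit_blr"
  )
}

#' Logistic risk probability
#'
#' `P(x) = exp(a + b x) / (1 + exp(a + b x))`.
#'
#' @param x Metric values.
#' @param a,b Logistic coefficients (or a `risk_fit_blr` passed as `a`).
#' @return Probability of injury in `(0, 1)`.
#' @export
blr_probability <- function(x, a, b = NULL) {
  if (inherits(a, "risk_fit_blr")) {
    b <- a$b
    a <- a$a
  }
  stats::plogis(a + b * x)
}

#' Censored Weibull survival risk fit
#'
#' Maximum-likelihood fit of the Weibull risk curve
#' `P(x) = 1 - exp(-(x / alpha)^beta)` (0 for `x < 0`) under the standard
#' injury-risk-curve censoring convention: an injured subject's tolerance is
#' left-censored at its metric value (injury occurred at or below `x`), a
#' non-injured subject's is right-censored (tolerance above `x`). Fitted by
#' direct likelihood maximization over `(log alpha, log beta)`.
#'
#' @param x Non-negative metric values.
#' @param y Binary labels (1 = injured).
#' @return A list of class `risk_fit_weibull` with `alpha`, `beta`,
#'   `loglik`, `aic`, `converged`.
#' @export
fit_weibull <- function(x, y) {
  y <- .check_two_classes(y)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(x >= 0))
  if (any(y == 1 & x <= 0)) {
    # a left-censored observation at 0 has zero likelihood under any
    # Weibull; floor such values at half the smallest positive metric value
    floor_x <- if (any(x > 0)) min(x[x > 0]) / 2 else 1e-6
    x[y == 1 & x <= 0] <- floor_x
  }
  negll <- function(theta) {
    alpha <- exp(theta[1])
    beta <- exp(theta[2])
    H <- (x / alpha)^beta
    ll <- sum(log(pmax(-expm1(-H[y == 1]), 1e-300))) - sum(H[y == 0])
    if (!is.finite(ll)) 1e10 else -ll
  }
  start <- c(log(max(mean(x), 1e-6)), 0)
  res <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(
    list(alpha = exp(res$par[1]), beta = exp(res$par[2]),
         loglik = -res$value, aic = 2 * 2 + 2 * res$value,
         converged = res$convergence == 0),
    class = "risk_fit_weibull"
  )
}

#' Weibull risk probability
#'
#' `P(x) = 1 - exp(-(x/alpha)^beta)` for `x >= 0`, zero otherwise.
#'
#' @param x Metric values.
#' @param alpha,beta Weibull scale and shape (or a `risk_fit_weibull` as
#'   `alpha`).
#' @return Probability of injury.
#' @export
weibull_probability <- function(x, alpha, beta = NULL) {
  if (inherits(alpha, "risk_fit_weibull")) {
    beta <- alpha$beta
    alpha <- alpha$alpha
  }
  ifelse(x < 0, 0, -expm1(-(pmax(x, 0) / alpha)^beta))
}

#' Metric value at 50% injury risk
#'
#' For a logistic fit, `-a/b`; for a Weibull fit,
#' `alpha * log(2)^(1/beta)`.
#'
#' @param fit A `risk_fit_blr` or `risk_fit_weibull`.
#' @return The 50%-risk threshold in metric units.
#' @export
threshold_50 <- function(fit) {
  if (inherits(fit, "risk_fit_blr")) {
    if (fit$b == 0) stop("slope is zero; 50% threshold undefined", call. = FALSE)
    return(-fit$a / fit$b)
  }
  if (inherits(fit, "risk_fit_weibull")) {
    return(fit$alpha * log(2)^(1 / fit$beta))
  }
  stop("`fit` must be a risk_fit_blr or risk_fit_weibull", call. = FALSE)
}

#' Empirical ROC curve
#'
#' Builds the empirical receiver operating characteristic over all
#' candidate thresholds (midpoints between adjacent distinct metric values,
#' plus sentinels below the minimum and above the maximum; predicted
#' injured iff `x > threshold`). AUROC is the trapezoidal area, which
#' equals the pairwise concordance probability with ties counted 1/2.
#'
#' @param x Metric values.
#' @param y Binary labels (1 = injured).
#' @return A list of class `roc_result` with `points` (data frame:
#'   `threshold`, `sensitivity`, `specificity`) and `auroc`.
#' @export
roc_curve <- function(x, y) {
  y <- .check_two_classes(y)
  stopifnot(length(x) == length(y), all(is.finite(x)))
  v <- sort(unique(x))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, v[length(v)] + 1)
  P <- sum(y == 1)
  N <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(x > t & y == 1) / P, 0)
  spec <- vapply(thr, function(t) sum(x <= t & y == 0) / N, 0)
  # integrate TPR over FPR (points ordered by decreasing threshold)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auroc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(
    list(points = data.frame(threshold = thr, sensitivity = sens,
                             specificity = spec),
         auroc = auroc),
    class = "roc_result"
  )
}

#' Optimal ROC threshold (closest to the perfect-classification corner)
#'
#' Selects the threshold whose (1 - specificity, sensitivity) point lies
#' closest (Euclidean) to (0, 1), weighting sensitivity and specificity
#' equally. Ties are broken by higher sensitivity, then by the lower
#' threshold.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return The optimal threshold (a midpoint between adjacent distinct
#'   metric values).
#' @export
optimal_roc_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points
  if (nrow(p) == 0) stop("empty ROC", call. = FALSE)
  d2 <- (1 - p$specificity)^2 + (1 - p$sensitivity)^2
  ord <- order(d2, -p$sensitivity, p$threshold)
  p$threshold[ord[1]]
}

#' Classify at a threshold and score the prediction
#'
#' Predicts injured iff `x > threshold` (ties count as negative) and
#' returns the confusion counts with sensitivity `S = TP/P`, specificity
#' `SP = TN/N` and overall prediction accuracy rate
#' `PAR = (TP + TN)/(P + N)`.
#'
#' @param x Metric values.
#' @param y Binary labels (1 = injured).
#' @param threshold Classification threshold.
#' @return A list of class `confusion_counts` with `TP`, `TN`, `P`, `N`,
#'   `S`, `SP`, `PAR`.
#' @export
classify_and_score <- function(x, y, threshold) {
  y <- .check_two_classes(y)
  stopifnot(length(x) == length(y), is.finite(threshold))
  pred <- as.integer(x > threshold)
  P <- sum(y == 1)
  N <- sum(y == 0)
  TP <- sum(pred == 1 & y == 1)
  TN <- sum(pred == 0 & y == 0)
  structure(
    list(TP = TP, TN = TN, P = P, N = N,
         S = TP / P, SP = TN / N, PAR = (TP + TN) / (P + N)),
    class = "confusion_counts"
  )
}
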