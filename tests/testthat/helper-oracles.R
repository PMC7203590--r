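# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, never through the package's own
# computational path.

# Cauchy stress by central finite differences of an energy function W(F):
# P_ij = dW/dF_ij, sigma = P F' / J.
fd_cauchy_stress <- function(F, W, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F
      Fm <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (W(Fp) - W(Fm)) / (2 * h)
    }
  }
  P %*% t(F) / det(F)
}

# Direct evaluation of the QLV hereditary integral for piecewise-linear
# elastic stress (exact closed form per interval), O(n^2).
qlv_direct <- function(sigma_e, g_inf, g, tau, dt) {
  n <- length(sigma_e)
  t_n <- (seq_len(n) - 1) * dt
  relax <- function(t) g_inf + sum(g * exp(-t / tau))
  out <- numeric(n)
  for (m in seq_len(n)) {
    acc <- relax(t_n[m]) * sigma_e[1]
    if (m > 1) {
      for (k in 2:m) {
        slope <- (sigma_e[k] - sigma_e[k - 1]) / dt
        seg <- g_inf * dt +
          sum(g * tau * (exp(-(t_n[m] - t_n[k]) / tau) -
                           exp(-(t_n[m] - t_n[k - 1]) / tau)))
        acc <- acc + slope * seg
      }
    }
    out[m] <- acc
  }
  out
}

# Logistic-regression MLE by Newton-Raphson on (a, b).
logistic_mle_nr <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    Wd <- p * (1 - p)
    score <- drop(t(X) %*% (y - p))
    info <- t(X) %*% (X * Wd)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta <- unname(beta)
  c(a = beta[1], b = beta[2])
}

# AUROC as the pairwise concordance probability (ties count 1/2).
concordance_auroc <- function(x, y) {
  xp <- x[y == 1]
  xn <- x[y == 0]
  tot <- 0
  for (p in xp) tot <- tot + sum(p > xn) + 0.5 * sum(p == xn)
  tot / (length(xp) * length(xn))
}

# Exhaustive optimal-ROC threshold: minimize distance of (1-SP, S) to (0,1)
# over midpoint thresholds, ties by higher S then lower threshold.
brute_force_roc_threshold <- function(x, y) {
  v <- sort(unique(x))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  best <- NULL
  for (t in thr) {
    S <- sum(x > t & y == 1) / sum(y == 1)
    SP <- sum(x <= t & y == 0) / sum(y == 0)
    d2 <- (1 - SP)^2 + (1 - S)^2
    cand <- c(d2 = d2, S = S, t = t)
    if (is.null(best) ||
        d2 < best["d2"] - 1e-15 ||
        (abs(d2 - best["d2"]) < 1e-15 && S > best["S"] + 1e-15) ||
        (abs(d2 - best["d2"]) < 1e-15 && abs(S - best["S"]) < 1e-15 &&
           t < best["t"])) {
      best <- cand
    }
  }
  unname(best["t"])
}

# Exhaustive two-sample KS statistic over every sample point.
brute_force_ks_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(p) {
    abs(mean(a <= p) - mean(b <= p))
  }, 0))
}

# A small labelled fixture with controllable overlap, for ROC/BLR tests.
# Values are kept non-negative (injury metrics are magnitudes).
make_fixture <- function(n_pos, n_neg, shift, seed) {
  set.seed(seed)
  x <- pmax(c(rnorm(n_neg, 5, 1), rnorm(n_pos, 5 + shift, 1)), 0.01)
  y <- c(rep(0L, n_neg), rep(1L, n_pos))
  list(x = x, y = y)
}

# Mean censored-Weibull MLE over independent replicate cohorts: the shape
# estimate from one binary-censored cohort has a few-percent sampling SD,
# so recovery checks average replicate fits.
replicate_weibull_fit <- function(n, alpha, beta, reps, seed) {
  set.seed(seed)
  est <- vapply(seq_len(reps), function(i) {
    x <- runif(n, 1, 9)
    y <- as.integer(rweibull(n, shape = beta, scale = alpha) <= x)
    f <- fit_weibull(x, y)
    c(f$alpha, f$beta)
  }, c(0, 0))
  rowMeans(est)
}

# Element-peak fixture where injury is driven by exceedance of a planted
# cutoff: subject-heterogeneous log-normal peaks, labels thresholded on the
# exceedance fraction at c_star.
planted_cutoff_fixture <- function(n_subj = 42, n_el = 400, c_star = 0.13,
                                   seed = 1) {
  set.seed(seed)
  peaks <- lapply(seq_len(n_subj), function(i) {
    med <- runif(1, 0.06, 0.20)
    sdl <- runif(1, 0.2, 0.6)
    rlnorm(n_el, log(med), sdl)
  })
  f <- vapply(peaks, function(p) mean(p > c_star), 0)
  y <- as.integer(f > stats::median(f))
  list(peaks = peaks, labels = y, c_star = c_star, fractions = f)
}
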