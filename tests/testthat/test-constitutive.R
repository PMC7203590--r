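# Material-point model: dispersion mapping, energies, stresses, QLV and
# calibration.

test_that("FA-to-kappa mapping hits its endpoints and is monotone", {
  expect_identical(kappa_from_fa(1), 0)
  expect_equal(kappa_from_fa(0), 1 / 3)
  expect_equal(kappa_from_fa(0.5), 0.2279241, tolerance = 1e-6)

  fa <- seq(0, 1, length.out = 501)
  k <- kappa_from_fa(fa)
  expect_true(all(k >= 0 & k <= 1 / 3))
  expect_true(all(diff(k) <= 1e-12))

  expect_error(kappa_from_fa(-0.1), "0, 1")
  expect_error(kappa_from_fa(1.1), "0, 1")
})

test_that("isochoric invariants split volume change from distortion", {
  iv <- isochoric_invariants(diag(3))
  expect_equal(iv$J, 1)
  expect_equal(iv$I1_bar, 3)
  expect_equal(iv$C_bar, diag(3))

  iv <- isochoric_invariants(2 * diag(3))
  expect_equal(iv$J, 8)
  expect_equal(iv$C_bar, diag(3))
  expect_equal(iv$I1_bar, 3)

  Fs <- diag(3)
  Fs[1, 2] <- 0.5
  iv <- isochoric_invariants(Fs)
  expect_equal(iv$J, 1)
  expect_equal(iv$I1_bar, 3.25)

  expect_error(isochoric_invariants(matrix(0, 3, 3)), "positive")
  expect_error(isochoric_invariants(matrix(NaN, 3, 3)), "finite")
})

test_that("matrix energy vanishes at identity and under rigid motion", {
  p <- default_matrix_params()
  expect_equal(matrix_energy(diag(3), p), 0)

  set.seed(11)
  for (i in 1:20) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    expect_lt(abs(matrix_energy(R, p)), 1e-10)
    # invariance to superposed rotation of a strained state
    Fs <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
    if (det(Fs) <= 0) next
    expect_equal(matrix_energy(R %*% Fs, p), matrix_energy(Fs, p),
                 tolerance = 1e-10)
  }
})

test_that("matrix energy in simple shear matches the closed form", {
  p <- default_matrix_params()
  Fs <- diag(3)
  Fs[1, 2] <- 0.1
  # (G/2) gamma^2 + (k1/2) ((1/3) gamma^2)^2 in the k2 -> 0 limit
  expect_equal(matrix_energy(Fs, p),
               p$G / 2 * 0.01 + p$k1 / 2 * (0.01 / 3)^2,
               tolerance = 1e-12)
})

test_that("matrix stress agrees with finite differences of the energy", {
  p <- default_matrix_params()
  # huge K makes FD ill-conditioned; use a same-order bulk modulus here
  p_soft <- matrix_params(G = 3.0478, K = 50, k1 = 35.767, k2 = 0.5)
  set.seed(21)
  for (i in 1:50) {
    Fs <- diag(3) + matrix(rnorm(9, 0, 0.06), 3)
    if (det(Fs) <= 0.1) next
    sig <- matrix_instantaneous_stress(Fs, p_soft)
    ref <- fd_cauchy_stress(Fs, function(X) matrix_energy(X, p_soft))
    expect_equal(sig, (ref + t(ref)) / 2, tolerance = 1e-4)
    expect_equal(sig, t(sig))
  }
  expect_equal(matrix_instantaneous_stress(diag(3), p), matrix(0, 3, 3))
})

test_that("matrix stress reproduces small-strain shear and dilatation", {
  p <- default_matrix_params()
  Fs <- diag(3)
  Fs[1, 2] <- 0.01
  expect_equal(matrix_instantaneous_stress(Fs, p)[1, 2], p$G * 0.01,
               tolerance = 0.01)
  J <- 1.001
  Fd <- J^(1 / 3) * diag(3)
  expect_equal(mean(diag(matrix_instantaneous_stress(Fd, p))),
               p$K * (J^2 - 1) / (2 * J), tolerance = 1e-9)
})

test_that("fiber energy and stress follow the tension-only HGO form", {
  fp <- fiber_params(k1 = 43.432, k2 = 0, kappa = 0)
  expect_identical(fiber_energy(1, fp), 0)
  expect_identical(fiber_energy(0.95, fp), 0)
  expect_identical(fiber_instantaneous_stress(0.9, fp), 0)
  expect_equal(fiber_energy(1.1, fp), 43.432 / 2 * (1.1^2 - 1)^2,
               tolerance = 1e-12)
  expect_equal(fiber_instantaneous_stress(1.1, fp),
               2 * 43.432 * 1.1 * (1.1^2 - 1), tolerance = 1e-12)
  expect_error(fiber_energy(-1, fp), "positive")

  # compression carries energy when the tension-only rule is disabled
  fp2 <- fiber_params(k1 = 43.432, k2 = 0, kappa = 0, tension_only = FALSE)
  expect_gt(fiber_energy(0.9, fp2), 0)
})

test_that("fiber stress matches finite differences for dispersed fibers", {
  for (kap in c(0, 0.1, 1 / 3)) {
    fp <- fiber_params(k1 = 10, k2 = 0.8, kappa = kap)
    for (lam in c(1.02, 1.1, 1.3)) {
      h <- 1e-6
      fd <- (fiber_energy(lam + h, fp) - fiber_energy(lam - h, fp)) / (2 * h)
      expect_equal(fiber_instantaneous_stress(lam, fp), fd, tolerance = 1e-4)
    }
  }
})

test_that("energies and stresses are continuous across the k2 -> 0 switch", {
  lam <- 1.12
  W_lim <- fiber_energy(lam, fiber_params(k1 = 43.432, k2 = 0, kappa = 0))
  W_eps <- fiber_energy(lam, fiber_params(k1 = 43.432, k2 = 1e-9, kappa = 0))
  expect_equal(W_eps, W_lim, tolerance = 1e-8)

  s_lim <- fiber_instantaneous_stress(lam, fiber_params(k1 = 43.432, k2 = 0, kappa = 0))
  s_eps <- fiber_instantaneous_stress(lam, fiber_params(k1 = 43.432, k2 = 1e-9, kappa = 0))
  expect_equal(s_eps, s_lim, tolerance = 1e-8)

  Fs <- diag(3)
  Fs[1, 2] <- 0.2
  p_lim <- matrix_params(G = 3.0478, K = 50, k1 = 35.767, k2 = 0)
  p_eps <- matrix_params(G = 3.0478, K = 50, k1 = 35.767, k2 = 1e-9)
  expect_equal(matrix_energy(Fs, p_eps), matrix_energy(Fs, p_lim),
               tolerance = 1e-8)
  expect_equal(matrix_instantaneous_stress(Fs, p_eps),
               matrix_instantaneous_stress(Fs, p_lim), tolerance = 1e-8)
})

test_that("QLV recursion matches closed forms and the direct convolution", {
  dt <- 1e-4
  pr <- prony_series(0.4, 0.6, 0.1)
  expect_equal(qlv_convolve(numeric(100), pr, dt), numeric(100))

  # step relaxation
  n <- round(0.1 / dt) + 1
  out <- qlv_convolve(rep(10, n), pr, dt)
  expect_equal(out[n], 10 * (0.4 + 0.6 * exp(-1)), tolerance = 1e-6)
  expect_equal(out[1], 10)

  # ramp
  pr2 <- prony_series(0.5, 0.5, 1)
  tt <- seq(0, 1, dt)
  out2 <- qlv_convolve(tt, pr2, dt)
  expect_equal(out2[length(tt)], 0.5 + 0.5 * (1 - exp(-1)), tolerance = 1e-6)

  # arbitrary smooth history vs O(n^2) direct hereditary integral
  tt <- seq(0, 0.05, dt)
  sig_e <- 3 * sin(60 * tt) + tt * 40
  pr3 <- prony_series(0.3, c(0.5, 0.2), c(0.01, 0.1))
  expect_equal(qlv_convolve(sig_e, pr3, dt),
               qlv_direct(sig_e, 0.3, c(0.5, 0.2), c(0.01, 0.1), dt),
               tolerance = 1e-10)

  # quasi-elastic limit
  expect_equal(qlv_convolve(sig_e, prony_series(1), dt), sig_e)
})

test_that("non-normalized Prony coefficients are renormalized with a warning", {
  expect_warning(pr <- prony_series(0.109, 0.8909, 0.035), "renormaliz")
  expect_equal(pr$g_inf + sum(pr$g), 1)
  expect_silent(prony_series(0.5, 0.5, 1))
})

test_that("calibration recovers generating parameters from noise-free data", {
  truth <- default_matrix_params()
  recs <- gen_calibration_data(truth, rates = c(30, 90), gamma_max = 0.5,
                               noise_sd = 0, seed = 5)
  init <- matrix_params(G = truth$G * 1.3, K = truth$K,
                        k1 = truth$k1 * 0.7, k2 = 0, prony = truth$prony)
  fit <- calibrate_matrix(recs, init, fit = c("G", "k1"))
  expect_lt(abs(fit$params$G - truth$G) / truth$G, 0.01)
  expect_lt(abs(fit$params$k1 - truth$k1) / truth$k1, 0.01)
  expect_lte(fit$sse, fit$sse_init)

  # starting at the truth, the initial SSE is already (numerically) zero
  fit0 <- calibrate_matrix(recs, truth, fit = c("G", "k1"))
  expect_lt(fit0$sse_init, 1e-12)
})

test_that("calibration SSE settles at the noise floor", {
  truth <- default_matrix_params()
  recs <- gen_calibration_data(truth, rates = 50, gamma_max = 0.5,
                               dt = 5e-5, noise_sd = 0.02, seed = 6)
  m <- nrow(recs[[1]])
  init <- matrix_params(G = truth$G * 1.2, K = truth$K,
                        k1 = truth$k1 * 0.8, k2 = 0, prony = truth$prony)
  fit <- calibrate_matrix(recs, init, fit = c("G", "k1"))
  expect_lt(abs(fit$sse - m * 0.02^2) / (m * 0.02^2), 0.25)
})

test_that("calibration is deterministic and rejects non-uniform time grids", {
  truth <- default_matrix_params()
  recs <- gen_calibration_data(truth, rates = 40, noise_sd = 0.01, seed = 9)
  init <- matrix_params(G = 4, K = truth$K, k1 = 30, k2 = 0, prony = truth$prony)
  f1 <- calibrate_matrix(recs, init)
  f2 <- calibrate_matrix(recs, init)
  expect_identical(f1$params$G, f2$params$G)

  bad <- recs[[1]]
  bad$time[3] <- bad$time[3] * 1.5
  expect_error(calibrate_matrix(bad, init), "uniform")
})

test_that("stiffness-ratio bookkeeping follows the embedded-element rule", {
  s <- stiffness_ratio_spec(g_ratio = 3, gamma_v = 0.5)
  expect_equal(s$R, 2)
  expect_equal(s$R_v, 4)
  s0 <- stiffness_ratio_spec(1, 0.5)
  expect_equal(s0$R, 0)
  expect_equal(s0$R_v, 0)
  expect_error(stiffness_ratio_spec(3, 0), "gamma_v")
  expect_equal(default_fiber_params()$k1, 43.432)
})

test_that("Green-log strain conversion round-trips and hits known values", {
  expect_identical(green_to_log_strain(0), 0)
  expect_equal(green_to_log_strain(0.18), log(sqrt(1.36)), tolerance = 1e-12)
  expect_equal(round(green_to_log_strain(0.18), 2), 0.15)
  expect_equal(green_to_log_strain(0.21), log(sqrt(1.42)), tolerance = 1e-12)
  E <- seq(-0.4, 2, by = 0.1)
  expect_equal(log_to_green_strain(green_to_log_strain(E)), E,
               tolerance = 1e-12)
  expect_error(green_to_log_strain(-0.5), "exceed")
})

test_that("material configs survive a write/read round trip", {
  p <- default_matrix_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_material_config(p, path)
  q <- read_material_config(path)
  expect_equal(q$G, p$G)
  expect_equal(q$prony$g, p$prony$g, tolerance = 1e-12)

  fp <- fiber_params(43.432, kappa = 0.21)
  write_material_config(fp, path)
  expect_equal(read_material_config(path)$kappa, 0.21)
})
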