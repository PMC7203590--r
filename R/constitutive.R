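# Material-point implementation of the fiber/matrix hyper-viscoelastic brain
# tissue model: HGO-type strain energies, quasilinear viscoelastic (QLV)
# relaxation, stress-strain conversions and least-squares calibration.

# k2 below this is treated as the analytic k2 -> 0 limit (avoids 0/0).
.K2_EPS <- 1e-8

#' Isotropic dispersion limit of the HGO fiber term
#'
#' The dispersion parameter at which the fiber term of the
#' Holzapfel-Gasser-Ogden (HGO) model degenerates to an isotropic
#' contribution. The isotropic matrix energy uses this constant as its
#' effective dispersion, so the matrix fiber-like term reads
#' `E = (1/3) * (I1_bar - 3)`.
#'
#' @export
KAPPA_ISO <- 1 / 3

#' Fiber dispersion parameter from fractional anisotropy
#'
#' Maps a diffusion-tensor-imaging fractional anisotropy (FA) value to the
#' HGO structure parameter kappa, assuming mechanical anisotropy mirrors
#' diffusion anisotropy. FA = 1 (perfectly aligned axons) gives kappa = 0;
#' FA = 0 (isotropically dispersed axons) gives kappa = 1/3.
#'
#' @param fa Fractional anisotropy, numeric vector in `[0, 1]`.
#' @return Dispersion parameter kappa in `[0, 1/3]`, same length as `fa`.
#' @examples
#' kappa_from_fa(c(0, 0.5, 1))
#' @export
kappa_from_fa <- function(fa) {
  if (!is.numeric(fa) || anyNA(fa) || any(fa < 0 | fa > 1)) {
    stop("`fa` must be numeric in [0, 1]", call. = FALSE)
  }
  k <- 0.5 * (-6 + 4 * fa^2 + 2 * sqrt(3 * fa^2 - 2 * fa^4)) / (-9 + 6 * fa^2)
  # clamp tiny negative round-off at FA = 1; "+ 0" normalizes IEEE -0
  pmin(pmax(k, 0), KAPPA_ISO) + 0
}

#' Normalized Prony relaxation series
#'
#' A reduced (normalized) relaxation function
#' `G(t) = g_inf + sum_i g_i * exp(-t / tau_i)` with `g_inf + sum(g) = 1`.
#' Coefficients that do not sum to one (e.g. relaxation moduli quoted in
#' stress units) are renormalized with a warning.
#'
#' @param g_inf Steady-state coefficient, `>= 0`.
#' @param g Vector of relaxation coefficients, `>= 0` (may be empty).
#' @param tau Vector of decay time constants in seconds, `> 0`, same length
#'   as `g`.
#' @return An object of class `prony_series`.
#' @export
prony_series <- function(g_inf, g = numeric(0), tau = numeric(0)) {
  stopifnot(length(g) == length(tau), g_inf >= 0, all(g >= 0), all(tau > 0))
  total <- g_inf + sum(g)
  if (total <= 0) stop("Prony coefficients must have a positive sum", call. = FALSE)
  if (abs(total - 1) > 1e-6) {
    warning(sprintf(
      "Prony coefficients sum to %.6g; renormalizing to a reduced relaxation function",
      total
    ), call. = FALSE)
  }
  structure(
    list(g_inf = g_inf / total, g = g / total, tau = tau),
    class = "prony_series"
  )
}

#' Brain tissue matrix material parameters
#'
#' Parameter set for the isotropic HGO hyperelastic matrix with QLV
#' relaxation: shear modulus `G`, bulk modulus `K`, fiber-like term
#' parameters `k1` (stress-like) and `k2` (dimensionless), a normalized
#' Prony series, and the mass density.
#'
#' @param G Shear modulus (kPa), `> 0`.
#' @param K Bulk modulus (kPa), `> 0`.
#' @param k1 Stress-like parameter (kPa), `>= 0`.
#' @param k2 Dimensionless exponent parameter, `>= 0`.
#' @param prony A [prony_series()]; default is the quasi-elastic series
#'   `g_inf = 1`.
#' @param density Mass density (g/cm^3), `> 0`.
#' @return An object of class `matrix_params`.
#' @seealso [default_matrix_params()] for the calibrated pig brain values.
#' @export
matrix_params <- function(G, K, k1 = 0, k2 = 0,
                          prony = prony_series(1), density = 1.04) {
  stopifnot(G > 0, K > 0, k1 >= 0, k2 >= 0, density > 0,
            inherits(prony, "prony_series"))
  structure(
    list(G = G, K = K, k1 = k1, k2 = k2, prony = prony, density = density),
    class = "matrix_params"
  )
}

#' Axonal fiber material parameters
#'
#' Parameter set for the anisotropic HGO fiber energy used for 1-D axonal
#' cable elements. The dispersion `kappa` may be given directly or derived
#' from a fractional anisotropy value via [kappa_from_fa()]; when both are
#' supplied they must agree.
#'
#' @param k1 Stress-like parameter (kPa), `>= 0`.
#' @param k2 Dimensionless exponent parameter, `>= 0`.
#' @param kappa Dispersion parameter in `[0, 1/3]`, or `NULL` to derive from
#'   `fa`.
#' @param fa Fractional anisotropy in `[0, 1]`, or `NULL`.
#' @param tension_only If `TRUE` (default) the fiber stores no energy and
#'   carries no stress in compression (`lambda <= 1`).
#' @param prony Normalized [prony_series()] for the fiber QLV response.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(k1, k2 = 0, kappa = NULL, fa = NULL,
                         tension_only = TRUE, prony = prony_series(1)) {
  stopifnot(k1 >= 0, k2 >= 0, inherits(prony, "prony_series"))
  if (is.null(kappa) && is.null(fa)) kappa <- 0
  if (!is.null(fa)) {
    stopifnot(fa >= 0, fa <= 1)
    kappa_fa <- kappa_from_fa(fa)
    if (!is.null(kappa) && abs(kappa - kappa_fa) > 1e-6) {
      stop("`kappa` is inconsistent with the value implied by `fa`", call. = FALSE)
    }
    kappa <- kappa_fa
  }
  stopifnot(kappa >= 0, kappa <= KAPPA_ISO + 1e-12)
  structure(
    list(k1 = k1, k2 = k2, kappa = kappa, fa = fa,
         tension_only = isTRUE(tension_only), prony = prony),
    class = "fiber_params"
  )
}

#' Calibrated pig brain matrix parameters
#'
#' The default matrix parameter fixture: shear modulus 3.0478 kPa, bulk
#' modulus 2.19 GPa, k1 = 35.767 kPa with k2 -> 0, single-term Prony series
#' (g1 = 0.8909, g_inf = 0.109 after normalization, tau = 0.035 s) and
#' density 1.04 g/cm^3.
#'
#' @return A [matrix_params()] object.
#' @export
default_matrix_params <- function() {
  total <- 0.109 + 0.8909
  matrix_params(
    G = 3.0478, K = 2.19e6, k1 = 35.767, k2 = 0,
    prony = prony_series(g_inf = 0.109 / total, g = 0.8909 / total, tau = 0.035),
    density = 1.04
  )
}

#' Default axonal fiber parameters
#'
#' The default fiber fixture: k1 = 43.432 kPa, k2 -> 0, tension-only, with
#' dispersion left to be set per element from its FA value.
#'
#' @param fa Optional fractional anisotropy for the element; if omitted the
#'   fiber is treated as perfectly aligned (kappa = 0).
#' @return A [fiber_params()] object.
#' @export
default_fiber_params <- function(fa = NULL) {
  fiber_params(k1 = 43.432, k2 = 0, kappa = if (is.null(fa)) 0 else NULL,
               fa = fa, tension_only = TRUE)
}

# exponential fiber-term energy k1/(2 k2) (exp(k2 E^2) - 1) with analytic
# k2 -> 0 limit (k1/2) E^2
.hgo_term_energy <- function(k1, k2, E) {
  if (k2 < .K2_EPS) k1 / 2 * E^2 else k1 / (2 * k2) * (exp(k2 * E^2) - 1)
}

# derivative of .hgo_term_energy with respect to E
.hgo_term_dE <- function(k1, k2, E) {
  if (k2 < .K2_EPS) k1 * E else k1 * E * exp(k2 * E^2)
}

#' Isochoric deformation invariants
#'
#' Splits a deformation gradient into its volumetric and isochoric parts and
#' returns the invariants the matrix and fiber energies consume.
#'
#' @param F A 3x3 deformation gradient with positive determinant.
#' @return A list with `J` (volume ratio, `det F`), `C_bar` (isochoric right
#'   Cauchy-Green tensor `J^(-2/3) F'F`) and `I1_bar` (its trace).
#' @export
isochoric_invariants <- function(F) {
  if (!is.matrix(F) || !all(dim(F) == c(3, 3)) || !all(is.finite(F))) {
    stop("`F` must be a finite 3x3 matrix", call. = FALSE)
  }
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("det(F) must be positive", call. = FALSE)
  C_bar <- J^(-2 / 3) * crossprod(F)
  list(J = J, C_bar = C_bar, I1_bar = sum(diag(C_bar)))
}

#' Matrix strain-energy density
#'
#' Isotropic HGO strain energy of the brain tissue matrix,
#' `W = G/2 (I1_bar - 3) + K ((J^2 - 1)/4 - ln(J)/2)
#'    + k1/(2 k2) (exp(k2 E^2) - 1)` with `E = (1/3)(I1_bar - 3)`,
#' i.e. the fiber term evaluated at the isotropic dispersion limit
#' [KAPPA_ISO]. The `k2 -> 0` analytic limit `(k1/2) E^2` is used below a
#' small tolerance.
#'
#' @param F 3x3 deformation gradient.
#' @param params A [matrix_params()] object.
#' @return Strain-energy density in kPa (non-negative, zero at identity).
#' @export
matrix_energy <- function(F, params) {
  stopifnot(inherits(params, "matrix_params"))
  inv <- isochoric_invariants(F)
  E <- KAPPA_ISO * (inv$I1_bar - 3)
  params$G / 2 * (inv$I1_bar - 3) +
    params$K * ((inv$J^2 - 1) / 4 - log(inv$J) / 2) +
    .hgo_term_energy(params$k1, params$k2, E)
}

#' Instantaneous Cauchy stress of the matrix model
#'
#' Analytic Cauchy stress derived from [matrix_energy()]:
#' `sigma = (2/J) psi1 dev(B_bar) + K (J^2 - 1)/(2J) I`, where
#' `psi1 = dW/dI1_bar` collects the shear and dispersion-limit fiber terms.
#'
#' @param F 3x3 deformation gradient.
#' @param params A [matrix_params()] object.
#' @return Symmetric 3x3 Cauchy stress tensor (kPa).
#' @export
matrix_instantaneous_stress <- function(F, params) {
  stopifnot(inherits(params, "matrix_params"))
  inv <- isochoric_invariants(F)
  J <- inv$J
  B_bar <- J^(-2 / 3) * tcrossprod(F)
  E <- KAPPA_ISO * (inv$I1_bar - 3)
  psi1 <- params$G / 2 + .hgo_term_dE(params$k1, params$k2, E) * KAPPA_ISO
  dev_B <- B_bar - inv$I1_bar / 3 * diag(3)
  sig <- 2 / J * psi1 * dev_B + params$K * (J^2 - 1) / (2 * J) * diag(3)
  (sig + t(sig)) / 2
}

#' Fiber strain-energy density for a 1-D cable element
#'
#' HGO fiber energy `W = k1/(2 k2) (exp(k2 E^2) - 1)` with the dispersed
#' fiber strain `E = kappa (I1_bar - 3) + (1 - 3 kappa)(I4_bar - 1)`.
#' For cable kinematics there is no volumetric split and `I4_bar = lambda^2`
#' with `lambda` the axial stretch. When `I1_bar` is not supplied it is taken
#' from the isochoric uniaxial state `lambda^2 + 2/lambda` (irrelevant when
#' `kappa = 0`). Under the tension-only rule the energy is zero for
#' `lambda <= 1`.
#'
#' @param lambda Axial stretch, `> 0`.
#' @param params A [fiber_params()] object.
#' @param I1_bar Optional first isochoric invariant of the host deformation;
#'   treated as independent of `lambda`.
#' @return Strain-energy density in kPa.
#' @export
fiber_energy <- function(lambda, params, I1_bar = NULL) {
  stopifnot(inherits(params, "fiber_params"))
  if (!is.numeric(lambda) || anyNA(lambda) || any(lambda <= 0)) {
    stop("`lambda` must be a positive stretch", call. = FALSE)
  }
  I1 <- if (is.null(I1_bar)) lambda^2 + 2 / lambda else I1_bar
  E <- params$kappa * (I1 - 3) + (1 - 3 * params$kappa) * (lambda^2 - 1)
  W <- vapply(E, function(e) .hgo_term_energy(params$k1, params$k2, e), 0)
  if (params$tension_only) W[lambda <= 1] <- 0
  W
}

#' Instantaneous axial fiber stress
#'
#' Nominal (first Piola-Kirchhoff) axial stress `dW/dlambda` of
#' [fiber_energy()]. Zero in compression under the tension-only rule. For
#' `kappa = 0` and `k2 -> 0` this reduces to `2 k1 lambda (lambda^2 - 1)`.
#'
#' @inheritParams fiber_energy
#' @return Axial nominal stress in kPa.
#' @export
fiber_instantaneous_stress <- function(lambda, params, I1_bar = NULL) {
  stopifnot(inherits(params, "fiber_params"))
  if (!is.numeric(lambda) || anyNA(lambda) || any(lambda <= 0)) {
    stop("`lambda` must be a positive stretch", call. = FALSE)
  }
  if (is.null(I1_bar)) {
    I1 <- lambda^2 + 2 / lambda
    dI1 <- 2 * lambda - 2 / lambda^2
  } else {
    I1 <- I1_bar
    dI1 <- 0
  }
  E <- params$kappa * (I1 - 3) + (1 - 3 * params$kappa) * (lambda^2 - 1)
  dE <- params$kappa * dI1 + (1 - 3 * params$kappa) * 2 * lambda
  s <- vapply(seq_along(E), function(i) {
    .hgo_term_dE(params$k1, params$k2, E[i]) * dE[i]
  }, 0)
  if (params$tension_only) s[lambda <= 1] <- 0
  s
}

#' Quasilinear viscoelastic stress from an elastic stress history
#'
#' Evaluates the QLV hereditary integral
#' `sigma(t) = int_0^t G(t - s) d sigma_e/ds ds` with the normalized reduced
#' relaxation function of a [prony_series()], on a uniform time grid. Uses a
#' recursive internal-variable update that is exact when the elastic stress
#' is piecewise linear between samples; a step at `t = 0` (a nonzero first
#' sample) is treated as an instantaneous jump.
#'
#' @param sigma_e Numeric vector: instantaneous deviatoric elastic stress at
#'   uniform time steps (kPa).
#' @param prony A [prony_series()].
#' @param dt Time step in seconds, `> 0`.
#' @return Numeric vector of viscoelastic stress, same length as `sigma_e`.
#' @export
qlv_convolve <- function(sigma_e, prony, dt) {
  stopifnot(inherits(prony, "prony_series"), is.numeric(dt), dt > 0)
  if (!is.numeric(sigma_e) || !all(is.finite(sigma_e))) {
    stop("`sigma_e` must be a finite numeric vector", call. = FALSE)
  }
  n <- length(sigma_e)
  out <- prony$g_inf * sigma_e
  for (i in seq_along(prony$g)) {
    a <- exp(-dt / prony$tau[i])
    b <- prony$g[i] * prony$tau[i] / dt * (1 - a)
    h <- numeric(n)
    h[1] <- prony$g[i] * sigma_e[1]
    if (n > 1) {
      d <- diff(sigma_e)
      for (k in 2:n) h[k] <- a * h[k - 1] + b * d[k - 1]
    }
    out <- out + h
  }
  out
}

#' Elastic shear stress of the matrix model in simple shear
#'
#' Closed-form shear component of [matrix_instantaneous_stress()] for simple
#' shear with engineering shear strain `gamma`:
#' `sigma_12 = G gamma + (2 k1 / 9) gamma^3 exp(k2 gamma^4 / 9)` (the
#' exponential factor absent in the `k2 -> 0` limit). Used as the forward
#' model for calibration against constant-rate shear records.
#'
#' @param gamma Engineering shear strain (numeric vector).
#' @param params A [matrix_params()] object.
#' @return Shear stress in kPa.
#' @export
matrix_shear_stress <- function(gamma, params) {
  stopifnot(inherits(params, "matrix_params"))
  E <- KAPPA_ISO * gamma^2
  psi1 <- params$G / 2 +
    KAPPA_ISO * vapply(E, function(e) .hgo_term_dE(params$k1, params$k2, e), 0)
  2 * psi1 * gamma
}

#' Calibrate matrix parameters against stress records
#'
#' Bounded nonlinear least squares on one or more shear stress records
#' (`time`, `strain`, `stress` columns; `strain` is engineering shear). The
#' forward model is [matrix_shear_stress()] run through [qlv_convolve()] with
#' the Prony series of `init`. Only the parameters named in `fit` are
#' adjusted; the sum of squared errors (SSE) at the solution never exceeds
#' the SSE at `init`.
#'
#' @param records A data frame or list of data frames with columns `time`
#'   (s, uniform grid), `strain`, `stress` (kPa).
#' @param init A [matrix_params()] object used as starting point.
#' @param fit Character vector of parameter names to fit, a subset of
#'   `c("G", "K", "k1", "k2")`.
#' @param lower,upper Named bounds for the fitted parameters (defaults span
#'   a wide positive range).
#' @return A list with `params` (fitted [matrix_params()]), `sse`,
#'   `sse_init`, `converged` and the raw `optim` convergence code.
#' @export
calibrate_matrix <- function(records, init, fit = c("G", "k1"),
                             lower = NULL, upper = NULL) {
  stopifnot(inherits(init, "matrix_params"))
  if (is.data.frame(records)) records <- list(records)
  if (length(records) < 1) stop("at least one record is required", call. = FALSE)
  for (r in records) {
    stopifnot(all(c("time", "strain", "stress") %in% names(r)))
    if (nrow(r) > 2 && diff(range(diff(r$time))) > 1e-9 * max(diff(r$time))) {
      stop("record time grids must be uniform", call. = FALSE)
    }
  }
  fit <- match.arg(fit, c("G", "K", "k1", "k2"), several.ok = TRUE)
  default_lower <- c(G = 1e-6, K = 1e-6, k1 = 0, k2 = 0)
  default_upper <- c(G = 1e9, K = 1e12, k1 = 1e9, k2 = 100)
  lo <- default_lower[fit]
  up <- default_upper[fit]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper

  with_theta <- function(theta) {
    p <- init
    p[fit] <- as.list(theta)
    p
  }
  sse_fun <- function(theta) {
    p <- with_theta(theta)
    sum(vapply(records, function(r) {
      sig_e <- matrix_shear_stress(r$strain, p)
      dt <- if (nrow(r) > 1) r$time[2] - r$time[1] else 1
      sum((qlv_convolve(sig_e, p$prony, dt) - r$stress)^2)
    }, 0))
  }
  theta0 <- unlist(init[fit])
  sse_init <- sse_fun(theta0)
  res <- stats::optim(theta0, sse_fun, method = "L-BFGS-B",
                      lower = lo, upper = up,
                      control = list(factr = 1e4, maxit = 500))
  if (res$value > sse_init) {
    res$par <- theta0
    res$value <- sse_init
  }
  list(params = with_theta(res$par), sse = res$value, sse_init = sse_init,
       converged = res$convergence == 0, status = res$convergence)
}

#' Effective stiffness ratio of embedded fibers
#'
#' Bookkeeping for the embedded-element stiffness correction: the excess
#' stiffness ratio `R = G_fiber/G_matrix - 1` and the effective ratio
#' `R_v = R / gamma_v`, with `gamma_v` the fiber volume fraction. The mapping
#' from `R_v` to fiber stiffness parameters is deliberately configurable;
#' the shipped default fiber fixture is [default_fiber_params()]
#' (k1 = 43.432 kPa).
#'
#' @param g_ratio Fiber-to-matrix stiffness ratio `G_fiber/G_matrix`, `>= 1`.
#' @param gamma_v Fiber volume fraction in `(0, 1]`.
#' @return A list of class `stiffness_ratio_spec` with `g_ratio`, `gamma_v`,
#'   `R` and `R_v`.
#' @export
stiffness_ratio_spec <- function(g_ratio, gamma_v) {
  if (!is.numeric(gamma_v) || gamma_v <= 0 || gamma_v > 1) {
    stop("`gamma_v` must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(g_ratio >= 1)
  R <- g_ratio - 1
  structure(
    list(g_ratio = g_ratio, gamma_v = gamma_v, R = R, R_v = R / gamma_v),
    class = "stiffness_ratio_spec"
  )
}

#' Convert Green-Lagrange strain to logarithmic strain
#'
#' `e = ln(sqrt(1 + 2 E))`, defined for `E > -1/2`.
#'
#' @param E Green-Lagrange strain.
#' @return Logarithmic (true) strain.
#' @seealso [log_to_green_strain()] for the inverse.
#' @export
green_to_log_strain <- function(E) {
  if (!is.numeric(E) || anyNA(E) || any(E <= -0.5)) {
    stop("Green strain must exceed -1/2", call. = FALSE)
  }
  0.5 * log1p(2 * E)
}

#' Convert logarithmic strain to Green-Lagrange strain
#'
#' Inverse of [green_to_log_strain()]: `E = (exp(2 e) - 1) / 2`.
#'
#' @param e Logarithmic strain.
#' @return Green-Lagrange strain.
#' @export
log_to_green_strain <- function(e) {
  stopifnot(is.numeric(e), all(is.finite(e)))
  (exp(2 * e) - 1) / 2
}

#' Write material parameters to a flat JSON config
#'
#' @param params A [matrix_params()] or [fiber_params()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_material_config <- function(params, path) {
  stopifnot(inherits(params, c("matrix_params", "fiber_params")))
  flat <- unclass(params)
  flat$prony <- unclass(flat$prony)
  flat$.type <- class(params)[1]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read material parameters from a flat JSON config
#'
#' @param path File written by [write_material_config()].
#' @return A [matrix_params()] or [fiber_params()] object.
#' @export
read_material_config <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- prony_series(flat$prony$g_inf,
                     as.numeric(flat$prony$g),
                     as.numeric(flat$prony$tau))
  if (identical(flat$.type, "matrix_params")) {
    matrix_params(flat$G, flat$K, flat$k1, flat$k2, pr, flat$density)
  } else {
    fiber_params(flat$k1, flat$k2, kappa = flat$kappa,
                 tension_only = flat$tension_only, prony = pr)
  }
}
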