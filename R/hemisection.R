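# Model-validation procedure for the hemisection experiment: planar strain
# from ink-marker triads, cumulative strain distributions, and two-sample
# Kolmogorov-Smirnov comparison of simulated vs experimental strains.

#' Deformation gradient of a marker triad
#'
#' The unique 2-D linear map taking the two reference edge vectors of a
#' marker triangle onto their deformed images: `F [r1 r2] = [d1 d2]`.
#' Exact for affine motions of the plane.
#'
#' @param ref 3x2 matrix of reference marker coordinates (mm).
#' @param def 3x2 matrix of deformed marker coordinates (mm).
#' @return A 2x2 deformation gradient.
#' @export
triad_deformation <- function(ref, def) {
  ref <- as.matrix(ref)
  def <- as.matrix(def)
  stopifnot(all(dim(ref) == c(3, 2)), all(dim(def) == c(3, 2)),
            all(is.finite(ref)), all(is.finite(def)))
  Re <- cbind(ref[2, ] - ref[1, ], ref[3, ] - ref[1, ])
  De <- cbind(def[2, ] - def[1, ], def[3, ] - def[1, ])
  area2 <- abs(det(Re))
  if (area2 < 1e-10 * max(1, sum(Re^2))) {
    stop("reference markers are collinear", call. = FALSE)
  }
  De %*% solve(Re)
}

#' Principal strain of a 2-D deformation gradient
#'
#' Largest principal value of the Green-Lagrange strain `(C - I)/2` or the
#' logarithmic (Hencky) strain `log(C)/2`, with `C = F'F`. Objective:
#' invariant under superposed rotations `R F`.
#'
#' @param F2 2x2 deformation gradient.
#' @param measure `"green"` or `"log"`.
#' @return The largest principal strain (scalar).
#' @export
triad_strain <- function(F2, measure = c("green", "log")) {
  measure <- match.arg(measure)
  stopifnot(is.matrix(F2), all(dim(F2) == c(2, 2)), all(is.finite(F2)))
  ev <- eigen(crossprod(F2), symmetric = TRUE, only.values = TRUE)$values
  lam2 <- max(ev)
  if (measure == "green") (lam2 - 1) / 2 else 0.5 * log(lam2)
}

#' Triad strains over a marker field
#'
#' Applies [triad_deformation()] and [triad_strain()] to every triad of a
#' [gen_hemisection_markers()] field (or equivalent), per frame, and
#' returns either per-frame strains or the per-triad maximum over frames.
#'
#' @param field A `marker_field` (list with `reference`, `frames`,
#'   `triads`).
#' @param measure Strain measure, see [triad_strain()].
#' @param reduce `"max"` for the per-triad maximum over frames,
#'   `"final"` for the last frame, `"none"` for the full matrix.
#' @return A numeric vector (or triads x frames matrix for
#'   `reduce = "none"`).
#' @export
marker_field_strains <- function(field, measure = c("green", "log"),
                                 reduce = c("max", "final", "none")) {
  measure <- match.arg(measure)
  reduce <- match.arg(reduce)
  stopifnot(!is.null(field$reference), length(field$frames) >= 1,
            nrow(field$triads) >= 1)
  strains <- vapply(field$frames, function(frame) {
    apply(field$triads, 1, function(id) {
      triad_strain(triad_deformation(field$reference[id, ], frame[id, ]),
                   measure)
    })
  }, numeric(nrow(field$triads)))
  strains <- matrix(strains, nrow = nrow(field$triads))
  switch(reduce,
         max = apply(strains, 1, max),
         final = strains[, ncol(strains)],
         none = strains)
}

# one-sided tail of the asymptotic Kolmogorov distribution
.kolmogorov_p <- function(lambda, terms = 100L) {
  if (lambda < 1e-3) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The exact supremum difference `D = sup |ECDF_a - ECDF_b|` between the two
#' empirical cumulative distributions, with the p-value from the asymptotic
#' Kolmogorov distribution using the standard small-sample effective-size
#' correction `lambda = (sqrt(n_eff) + 0.12 + 0.11/sqrt(n_eff)) D`,
#' `n_eff = n_a n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples (nonempty).
#' @return A list with `D`, `p_value`, `n_eff`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("samples must be nonempty", call. = FALSE)
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  D <- max(abs(Fa - Fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  list(D = D, p_value = .kolmogorov_p(lambda), n_eff = n_eff)
}

#' Compare simulated and experimental strain distributions
#'
#' Builds both cumulative strain distributions, runs [ks_two_sample()], and
#' reports whether the simulation passes validation (the two curves are not
#' statistically different, `p > alpha`).
#'
#' @param sim,exp Numeric strain samples from the simulation and the
#'   experiment.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `validation_report` with `D`, `p_value`,
#'   `passed`, `alpha`, and `cdf` (data frame: `strain`, `sim`, `exp`).
#' @export
compare_sim_experiment <- function(sim, exp, alpha = 0.05) {
  ks <- ks_two_sample(sim, exp)
  pts <- sort(unique(c(sim, exp)))
  structure(
    list(D = ks$D, p_value = ks$p_value, passed = ks$p_value > alpha,
         alpha = alpha,
         cdf = data.frame(strain = pts,
                          sim = stats::ecdf(sim)(pts),
                          exp = stats::ecdf(exp)(pts))),
    class = "validation_report"
  )
}
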