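# Synthetic-data generators: a rotational-injury cohort, per-element strain
# histories, calibration records, hemisection marker fields and streamline
# sets, all pure functions of (config, seed) with recorded ground truth.

# Run code under a fixed seed without clobbering the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministically spawn sub-seeds below 2^31 from a master seed.
.spawn_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Synthetic cohort configuration
#'
#' Default study conditions for the synthetic rotational-injury cohort:
#' 42 subjects targeting 29 injured / 13 non-injured, peak angular velocity
#' 89.54-203.14 rad/s and peak angular acceleration 18.43-72.36 krad/s^2,
#' axonal injury volume (AIV) binarized at 0.26%, and a logistic generative
#' link between a latent severity-driven injury metric and AIV. The true
#' 50%-risk threshold `theta_star` (default 5.0 in metric units, a
#' MASxSR-like scale in 1/s) and the link slope are recorded as ground truth
#' for downstream recovery checks.
#'
#' @param n_subjects Cohort size.
#' @param n_injured,n_noninjured Target label counts under exact-count mode.
#' @param omega_range Peak angular velocity range (rad/s).
#' @param alpha_range Peak angular acceleration range (krad/s^2).
#' @param aiv_threshold AIV percentage below which a subject is labelled
#'   non-injured (default 0.26).
#' @param metric_name Name of the generative metric.
#' @param theta_star True 50%-risk metric threshold.
#' @param risk_slope Logistic link slope per metric unit (steep by default).
#' @param metric_range Metric values spanned as severity goes from its
#'   minimum to its maximum.
#' @param aiv_scale Multiplier `A0` in `AIV = A0 * g(metric) * exp(noise)`;
#'   the default 0.52 places the 50%-risk point exactly at the AIV label
#'   threshold.
#' @param aiv_noise_sd Log-scale standard deviation of the AIV noise.
#' @param n_brain,n_axonal Element counts for generated strain histories.
#' @param dt Output time step in seconds (default 1e-4, i.e. 0.1 ms).
#' @param peak_strain_per_severity Median brain-element peak strain per unit
#'   severity (severity is `omega_peak / 150`).
#' @param peak_sdlog Log-scale spread of per-element peak strains.
#' @param attenuation_shape `c(alpha, beta)` of the Beta-distributed
#'   axonal-to-brain peak attenuation (default mean 0.4).
#' @param alpha_omega_coupling Weight in `[0, 1]` coupling the peak angular
#'   acceleration draw to the peak velocity (faster pulses are sharper);
#'   0 draws them independently.
#' @param exact_counts Resample (bounded retries) until the injured /
#'   non-injured targets are met exactly.
#' @param max_retries Retry bound for exact-count mode.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 42L,
                          n_injured = 29L,
                          n_noninjured = 13L,
                          omega_range = c(89.54, 203.14),
                          alpha_range = c(18.43, 72.36),
                          aiv_threshold = 0.26,
                          metric_name = "MASxSR",
                          theta_star = 5.0,
                          risk_slope = 3.0,
                          metric_range = c(2.5, 11.5),
                          aiv_scale = 0.52,
                          aiv_noise_sd = 0.3,
                          n_brain = 2000L,
                          n_axonal = 1000L,
                          dt = 1e-4,
                          peak_strain_per_severity = 0.12,
                          peak_sdlog = 0.3,
                          attenuation_shape = c(4, 6),
                          alpha_omega_coupling = 0.7,
                          exact_counts = TRUE,
                          max_retries = 200L) {
  stopifnot(
    n_subjects >= 2, n_injured + n_noninjured == n_subjects,
    all(omega_range > 0), all(alpha_range > 0),
    aiv_threshold > 0, theta_star > 0, risk_slope > 0,
    diff(metric_range) > 0, aiv_scale > 0, aiv_noise_sd >= 0,
    n_brain >= 1, n_axonal >= 1, dt > 0,
    peak_strain_per_severity > 0, all(attenuation_shape > 0)
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' Isometric mass scale factor
#'
#' Scale factor for uniform, isometric mass scaling of a base geometry:
#' `lambda = (m_scaled / m_base)^(1/3)` applied equally on all three axes.
#'
#' @param m_scaled,m_base Brain masses (g), `> 0`.
#' @return The linear scale factor.
#' @export
mass_scale_factor <- function(m_scaled, m_base) {
  if (any(c(m_scaled, m_base) <= 0)) stop("masses must be positive", call. = FALSE)
  (m_scaled / m_base)^(1 / 3)
}

#' Haversine angular-velocity pulse
#'
#' Canonical kinematic input: `omega(t) = omega_peak * sin^2(pi t / T)` with
#' duration `T = pi * omega_peak / alpha_peak`, so the pulse starts and ends
#' at zero, peaks at `omega_peak`, and has maximum angular acceleration
#' `alpha_peak`.
#'
#' @param omega_peak Peak angular velocity (rad/s), `> 0`.
#' @param alpha_peak Peak angular acceleration (rad/s^2), `> 0`.
#' @param dt Sampling step (s), must resolve the pulse (`dt < T`).
#' @return A data frame with columns `time` (s) and `omega` (rad/s).
#' @export
gen_kinematics <- function(omega_peak, alpha_peak, dt = 1e-4) {
  stopifnot(omega_peak > 0, alpha_peak > 0, dt > 0)
  T_pulse <- pi * omega_peak / alpha_peak
  if (dt >= T_pulse) stop("`dt` must be smaller than the pulse duration", call. = FALSE)
  # include the mid-pulse and end points so the sampled trace attains its
  # analytic extremes exactly
  time <- sort(unique(c(seq(0, T_pulse, by = dt), T_pulse / 2, T_pulse)))
  data.frame(time = time, omega = omega_peak * sin(pi * time / T_pulse)^2)
}

.draw_cohort_once <- function(config) {
  n <- config$n_subjects
  omega <- stats::runif(n, config$omega_range[1], config$omega_range[2])
  sev01 <- (omega - config$omega_range[1]) / diff(config$omega_range)
  # peak acceleration tracks peak velocity (faster pulses are also sharper),
  # so strain-rate metrics co-vary with rotational severity
  w <- config$alpha_omega_coupling
  alpha01 <- pmin(pmax(w * sev01 + (1 - w) * stats::runif(n), 0), 1)
  alpha <- config$alpha_range[1] + diff(config$alpha_range) * alpha01
  metric <- config$metric_range[1] + diff(config$metric_range) * sev01
  g <- stats::plogis(config$risk_slope * (metric - config$theta_star))
  aiv <- config$aiv_scale * g * exp(stats::rnorm(n, 0, config$aiv_noise_sd))
  injured <- as.integer(aiv >= config$aiv_threshold)
  # age groups and rotation planes mirroring the reference animal dataset
  age <- rep(c("4wk", "2mo"), length.out = n)
  plane <- rep(c("axial", "sagittal"), length.out = n)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age_group = age, plane = plane,
    omega_peak = omega, alpha_peak = alpha,
    severity = omega / 150,
    metric_true = metric,
    aiv_percent = aiv,
    injured = injured
  )
}

#' Generate a synthetic rotational-injury cohort
#'
#' Draws per-subject head kinematics uniformly inside the configured ranges,
#' maps angular-velocity severity linearly to a latent injury metric, and
#' generates the axonal injury volume through a logistic link with
#' log-normal noise: `AIV = A0 * logistic(slope * (metric - theta_star)) *
#' exp(eps)`. Subjects with AIV below `aiv_threshold` are labelled
#' non-injured. Under `exact_counts` the cohort is redrawn (with spawned
#' sub-seeds, bounded retries) until the injured / non-injured targets are
#' met.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @return A data frame with one row per subject (columns `subject_id`,
#'   `age_group`, `plane`, `omega_peak`, `alpha_peak`, `severity`,
#'   `metric_true`, `aiv_percent`, `injured`), with the generative ground
#'   truth in `attr(, "ground_truth")`.
#' @export
gen_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- .spawn_seeds(seed, max(1L, config$max_retries))
  cohort <- NULL
  for (s in seeds) {
    cand <- .with_seed(s, .draw_cohort_once(config))
    if (!config$exact_counts ||
        (sum(cand$injured) == config$n_injured &&
         sum(1 - cand$injured) == config$n_noninjured)) {
      cohort <- cand
      break
    }
  }
  if (is.null(cohort)) {
    stop("exact injured/non-injured targets not met within `max_retries`; ",
         "targets may be infeasible under the configured link", call. = FALSE)
  }
  attr(cohort, "ground_truth") <- list(
    metric_name = config$metric_name,
    theta_star = config$theta_star,
    risk_slope = config$risk_slope,
    aiv_threshold = config$aiv_threshold
  )
  cohort
}

#' Generate per-element strain histories for one subject
#'
#' Builds brain-solid and axonal-cable element strain histories as scaled
#' haversine pulses `eps_i(t) = p_i * sin^2(pi t / T_strain)`, where the
#' strain transient `T_strain` is half the subject's kinematic pulse
#' duration (tissue strain transients are briefer than the loading pulse),
#' followed by a trailing quiet interval so strains return to zero. Per-element peaks `p_i` are log-normal with median
#' proportional to the subject's severity; axonal peaks are brain peaks
#' times a Beta-distributed attenuation factor (default mean 0.4),
#' reflecting tract-oriented strains lying well below principal strains.
#'
#' @param subject A single-row data frame from [gen_cohort()] (or any list
#'   with `omega_peak`, `alpha_peak`, `severity`).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param severity Optional severity override (a positive scalar).
#' @return A list of class `element_histories` with components `brain` and
#'   `axonal`, each a list with `dt`, `values` (elements x timesteps strain
#'   matrix) and `weights` (element volumes for brain, unit lengths for
#'   axonal), plus `T_pulse`.
#' @export
gen_element_histories <- function(subject, config = cohort_config(),
                                  seed = 1L, severity = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sev <- if (is.null(severity)) subject$severity else severity
  stopifnot(is.numeric(sev), sev > 0)
  .with_seed(seed, {
    T_pulse <- pi * subject$omega_peak / (subject$alpha_peak * 1000)
    # tissue strain transient is briefer than the loading pulse; half the
    # kinematic pulse keeps peak strain rates in the tens-to-hundreds 1/s
    T_strain <- T_pulse / 2
    n_t <- ceiling(1.25 * T_pulse / config$dt) + 1L
    time <- (seq_len(n_t) - 1L) * config$dt
    shape <- ifelse(time <= T_strain, sin(pi * pmin(time, T_strain) / T_strain)^2, 0)

    med <- config$peak_strain_per_severity * sev
    p_brain <- stats::rlnorm(config$n_brain, log(med), config$peak_sdlog)
    atten <- stats::rbeta(config$n_axonal, config$attenuation_shape[1],
                          config$attenuation_shape[2])
    p_ax <- p_brain[sample.int(config$n_brain, config$n_axonal, replace = TRUE)] * atten
    vol <- stats::rlnorm(config$n_brain, 0, 0.2)
    structure(
      list(
        brain = list(dt = config$dt, values = outer(p_brain, shape),
                     weights = vol),
        axonal = list(dt = config$dt, values = outer(p_ax, shape),
                      weights = rep(1, config$n_axonal)),
        T_pulse = T_pulse
      ),
      class = "element_histories"
    )
  })
}

#' Generate synthetic calibration records
#'
#' Forward-models constant-rate shear records with the package's own
#' constitutive chain ([matrix_shear_stress()] through [qlv_convolve()]) and
#' adds i.i.d. Gaussian noise; `noise_sd = 0` returns the exact model
#' output.
#'
#' @param params A [matrix_params()] object (the generating ground truth).
#' @param rates Shear strain rates (1/s), one record per rate.
#' @param gamma_max Final engineering shear strain of each ramp.
#' @param dt Sampling step (s).
#' @param noise_sd Standard deviation of additive stress noise (kPa).
#' @param seed Integer seed.
#' @return A list of data frames with columns `time`, `strain`, `stress`.
#' @export
gen_calibration_data <- function(params, rates = c(30, 60, 90),
                                 gamma_max = 0.5, dt = 1e-4,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(params, "matrix_params"), all(rates > 0), gamma_max > 0)
  .with_seed(seed, {
    lapply(rates, function(rate) {
      time <- seq(0, gamma_max / rate, by = dt)
      gamma <- rate * time
      stress <- qlv_convolve(matrix_shear_stress(gamma, params), params$prony, dt)
      data.frame(time = time, strain = gamma,
                 stress = stress + stats::rnorm(length(stress), 0, noise_sd))
    })
  })
}

#' Generate synthetic hemisection marker trajectories
#'
#' Emulates ink-marker tracking on a transected brain surface: a planar
#' reference marker grid deformed over frames by (i) a rigid rotation (zero
#' true strain), (ii) a uniform stretch `lambda` along x (true logarithmic
#' strain `ln lambda`), or (iii) a smooth heterogeneous displacement field.
#' Markers are grouped into consecutive non-collinear triads.
#'
#' @param n_markers Number of markers (`>= 3`).
#' @param mode One of `"rigid"`, `"stretch"`, `"heterogeneous"`.
#' @param lambda Stretch for `"stretch"` mode.
#' @param angle_deg Total rotation for `"rigid"` mode (degrees).
#' @param n_frames Number of deformed frames (deformation ramps linearly to
#'   its final value).
#' @param amplitude Displacement amplitude (mm) for `"heterogeneous"` mode.
#' @param seed Integer seed (marker placement jitter).
#' @return A list of class `marker_field` with `reference` (n x 2 matrix,
#'   mm), `frames` (list of n x 2 matrices), `triads` (integer matrix, one
#'   triad per row) and `mode`.
#' @export
gen_hemisection_markers <- function(n_markers = 30L,
                                    mode = c("stretch", "rigid", "heterogeneous"),
                                    lambda = 1.2, angle_deg = 30,
                                    n_frames = 5L, amplitude = 2,
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (n_markers < 3) stop("at least 3 markers are required", call. = FALSE)
  .with_seed(seed, {
    side <- ceiling(sqrt(n_markers))
    g <- expand.grid(x = seq(0, 30, length.out = side),
                     y = seq(0, 30, length.out = side))[seq_len(n_markers), ]
    ref <- as.matrix(g) + matrix(stats::runif(2 * n_markers, -1, 1), ncol = 2)
    deform <- function(p, frac) {
      switch(mode,
        rigid = {
          th <- frac * angle_deg * pi / 180
          R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
          p %*% t(R)
        },
        stretch = {
          lam <- 1 + frac * (lambda - 1)
          cbind(p[, 1] * lam, p[, 2])
        },
        heterogeneous = {
          a <- frac * amplitude
          cbind(p[, 1] + a * sin(p[, 2] / 10), p[, 2] + a * cos(p[, 1] / 12))
        }
      )
    }
    frames <- lapply(seq_len(n_frames), function(f) deform(ref, f / n_frames))
    triads <- matrix(seq_len(3 * (n_markers %/% 3)), ncol = 3, byrow = TRUE)
    ok <- apply(triads, 1, function(id) {
      e1 <- ref[id[2], ] - ref[id[1], ]
      e2 <- ref[id[3], ] - ref[id[1], ]
      abs(e1[1] * e2[2] - e1[2] * e2[1]) > 1e-6
    })
    structure(
      list(reference = ref, frames = frames, triads = triads[ok, , drop = FALSE],
           mode = mode, lambda = lambda, angle_deg = angle_deg),
      class = "marker_field"
    )
  })
}

#' Generate synthetic streamlines with FA profiles
#'
#' Smooth 3-D polylines built by a persistent random walk, each carrying FA
#' samples drawn inside one of the eight reference FA bins; bins are chosen
#' with the [fa_reference_distribution()] percentage weights so a large
#' discretized element set reproduces the reference frequencies.
#'
#' @param n Number of streamlines.
#' @param length_range Range of streamline arclengths (mm).
#' @param step Distance between consecutive polyline points (mm).
#' @param fa_jitter Half-width of the within-streamline FA variation.
#' @param seed Integer seed.
#' @return A list of `n` data frames with columns `x`, `y`, `z`, `fa`.
#' @export
gen_streamlines <- function(n = 100L, length_range = c(5, 25), step = 0.2,
                            fa_jitter = 0.02, seed = 1L) {
  stopifnot(n >= 1, all(length_range > 0), step > 0)
  ref <- fa_reference_distribution()
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      L <- stats::runif(1, length_range[1], length_range[2])
      n_pts <- max(2L, ceiling(L / step) + 1L)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(0, n_pts, 3)
      pts[1, ] <- stats::runif(3, 0, 50)
      for (k in 2:n_pts) {
        dir <- dir + stats::rnorm(3, 0, 0.15)
        dir <- dir / sqrt(sum(dir^2))
        pts[k, ] <- pts[k - 1, ] + step * dir
      }
      bin <- sample.int(8, 1, prob = ref$percent)
      fa_mid <- stats::runif(1, ref$fa_lo[bin] + fa_jitter,
                             ref$fa_hi[bin] - fa_jitter)
      fa <- pmin(1, pmax(0.2, fa_mid + stats::runif(n_pts, -fa_jitter, fa_jitter)))
      data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], fa = fa)
    })
  })
}
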