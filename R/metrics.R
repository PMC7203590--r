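# The 12 deformation-based injury metrics: 95th-percentile peak strain,
# strain rate and strain-times-strain-rate for brain solid and axonal cable
# elements, the six cumulative fraction metrics at cutoffs, and
# damaged-volume-fraction estimates.

#' Default fraction-metric cutoffs
#'
#' The optimal cutoff values of the six fraction-based metrics: brain
#' elements at MPS 0.30, MPSR 120 1/s, MPSxSR 28 1/s; axonal elements at
#' MAS 0.13, MASR 70 1/s, MASxSR 7.5 1/s.
#'
#' @return A named list of cutoffs.
#' @export
default_cutoffs <- function() {
  list(MPS = 0.30, MPSR = 120, MPSxSR = 28,
       MAS = 0.13, MASR = 70, MASxSR = 7.5)
}

#' Default cutoff sweep grids
#'
#' The cutoff ranges examined when optimizing the six fraction-based
#' metrics: MPS 0.14-0.34, MPSR 60-200 1/s, MPSxSR 4-32 1/s, MAS 0.10-0.22,
#' MASR 10-90 1/s, MASxSR 1-9 1/s, each discretized to `n` points.
#'
#' @param n Number of grid points per metric (default 11).
#' @return A named list of numeric grids.
#' @export
default_cutoff_grids <- function(n = 11L) {
  list(
    MPS = seq(0.14, 0.34, length.out = n),
    MPSR = seq(60, 200, length.out = n),
    MPSxSR = seq(4, 32, length.out = n),
    MAS = seq(0.10, 0.22, length.out = n),
    MASR = seq(10, 90, length.out = n),
    MASxSR = seq(1, 9, length.out = n)
  )
}

#' Moving-window-average smoothing
#'
#' Centered moving mean with an odd window (default 5 points). At the
#' series ends the window is truncated to the available indices, so the
#' first point of a series averages itself and the following
#' `(window - 1) / 2` points.
#'
#' @param x Numeric vector (or an elements x timesteps matrix, smoothed
#'   along time).
#' @param window Odd window length `>= 1`.
#' @return Smoothed series of the same shape.
#' @export
smooth_series <- function(x, window = 5L) {
  if (window < 1 || window %% 2 == 0) {
    stop("`window` must be odd and >= 1", call. = FALSE)
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1, smooth_series, window = window)))
  }
  n <- length(x)
  if (n < window) stop("series shorter than the smoothing window", call. = FALSE)
  if (window == 1) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' First-order discrete strain rate
#'
#' Forward difference `(x[i+1] - x[i]) / dt`, assigned to index `i`; the
#' output is one sample shorter than the input.
#'
#' @param x Numeric vector (or matrix, differenced along time).
#' @param dt Uniform time step (s), `> 0`.
#' @return Rate series (1/s) of length `n - 1`.
#' @export
discrete_rate <- function(x, dt) {
  stopifnot(is.numeric(dt), dt > 0)
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("need at least 2 timesteps", call. = FALSE)
    return((x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]) / dt)
  }
  if (length(x) < 2) stop("need at least 2 timesteps", call. = FALSE)
  diff(x) / dt
}

#' Strain times strain rate series
#'
#' Pointwise signed product of the smoothed strain and its forward-difference
#' rate, on the common index range (the rate at index `i` multiplies the
#' smoothed strain at index `i`).
#'
#' @param x Strain series (vector or elements x timesteps matrix).
#' @param dt Uniform time step (s).
#' @param window Smoothing window passed to [smooth_series()].
#' @return SxSR series (1/s), one sample shorter than the input.
#' @export
strain_times_rate <- function(x, dt, window = 5L) {
  s <- smooth_series(x, window)
  r <- discrete_rate(s, dt)
  if (is.matrix(s)) s[, -ncol(s), drop = FALSE] * r else s[-length(s)] * r
}

#' Per-element peak strain, strain rate and strain-times-rate
#'
#' For each element history, the maximum over time of (i) the raw strain,
#' (ii) the rate of the 5-point smoothed strain, and (iii) the signed
#' product of smoothed strain and rate.
#'
#' @param values Elements x timesteps strain matrix.
#' @param dt Uniform time step (s).
#' @param window Smoothing window.
#' @return A data frame with columns `peak_strain`, `peak_rate`,
#'   `peak_sxsr`, one row per element.
#' @export
element_peaks <- function(values, dt, window = 5L) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  s <- smooth_series(values, window)
  r <- discrete_rate(s, dt)
  sxsr <- s[, -ncol(s), drop = FALSE] * r
  data.frame(
    peak_strain = apply(values, 1, max),
    peak_rate = apply(r, 1, max),
    peak_sxsr = apply(sxsr, 1, max)
  )
}

#' Linear-interpolation 95th percentile
#'
#' The 95th percentile of per-element peaks, computed with the
#' linear-interpolation sample quantile and unweighted across elements.
#' Used in place of the 100th percentile to suppress isolated numerical
#' artifacts.
#'
#' @param peaks Numeric vector of per-element peak values.
#' @param prob Percentile (default 0.95).
#' @return A scalar.
#' @export
percentile95 <- function(peaks, prob = 0.95) {
  if (length(peaks) < 1) stop("`peaks` must be nonempty", call. = FALSE)
  unname(stats::quantile(peaks, prob, type = 7, names = FALSE))
}

#' Weighted fraction of elements exceeding a cutoff
#'
#' The share of elements whose peak strictly exceeds `cutoff`, weighted by
#' element volume for brain elements or unweighted (unit weights) for 1-mm
#' axonal elements.
#'
#' @param peaks Numeric vector of per-element peaks.
#' @param cutoff Finite cutoff value.
#' @param weights Non-negative element weights (default uniform).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_exceeding <- function(peaks, cutoff, weights = NULL) {
  stopifnot(is.finite(cutoff))
  if (is.null(weights)) weights <- rep(1, length(peaks))
  stopifnot(length(weights) == length(peaks), all(weights >= 0))
  tot <- sum(weights)
  if (tot <= 0) stop("weights must not all be zero", call. = FALSE)
  sum(weights[peaks > cutoff]) / tot
}

#' Damaged volume fraction from a fraction metric
#'
#' Converts an exceedance fraction into a damaged-volume-fraction (DVF)
#' estimate. Brain-element fractions are already volume fractions and pass
#' through; axonal-element fractions are multiplied by the axonal volume
#' fraction `gamma_v` (default 0.5).
#'
#' @param fraction Exceedance fraction in `[0, 1]` (or percent, returned on
#'   the same scale).
#' @param source `"brain"` or `"axonal"`.
#' @param gamma_v Axonal fiber volume fraction.
#' @return DVF on the scale of `fraction`.
#' @export
dvf_from_fraction <- function(fraction, source = c("brain", "axonal"),
                              gamma_v = 0.5) {
  source <- match.arg(source)
  stopifnot(all(fraction >= 0))
  if (source == "axonal") fraction * gamma_v else fraction
}

#' Per-subject table of the 12 injury metrics
#'
#' Computes, for each subject's element histories, the six 95th-percentile
#' magnitude metrics (MPS, MPSR, MPSxSR over brain elements; MAS, MASR,
#' MASxSR over axonal elements), the six fraction metrics at the supplied
#' cutoffs (volume-weighted for brain, count-weighted for axonal), and the
#' corresponding DVF estimates.
#'
#' @param histories A named list of `element_histories` objects (one per
#'   subject, see [gen_element_histories()]), or a function
#'   `function(subject_id)` returning one.
#' @param subject_ids Subject identifiers (required when `histories` is a
#'   function; otherwise defaults to `names(histories)`).
#' @param cutoffs Named list of cutoffs as in [default_cutoffs()].
#' @param gamma_v Axonal volume fraction for DVF estimates.
#' @param window Smoothing window for the rate metrics.
#' @return A data frame with one row per subject: `subject_id`, the 12
#'   metric columns (`MPS`, `MPSR`, `MPSxSR`, `MAS`, `MASR`, `MASxSR`,
#'   `BF_MPS30`-style fraction columns named from the cutoffs) and six
#'   `DVF_` columns (percent).
#' @export
subject_metric_table <- function(histories, subject_ids = NULL,
                                 cutoffs = default_cutoffs(),
                                 gamma_v = 0.5, window = 5L) {
  if (is.function(histories)) {
    if (is.null(subject_ids)) stop("`subject_ids` required with a generator function",
                                   call. = FALSE)
    fetch <- histories
  } else {
    if (is.null(subject_ids)) subject_ids <- names(histories)
    if (is.null(subject_ids)) subject_ids <- as.character(seq_along(histories))
    fetch <- function(id) histories[[id]]
  }
  frac_name <- function(prefix, metric) {
    # strain cutoffs are conventionally quoted in percent (MPS 0.30 -> "30")
    c_lab <- if (metric %in% c("MPS", "MAS")) 100 * cutoffs[[metric]] else cutoffs[[metric]]
    sprintf("%s_%s%g", prefix, metric, c_lab)
  }
  rows <- lapply(subject_ids, function(id) {
    h <- fetch(id)
    if (is.null(h)) return(NULL)
    bp <- element_peaks(h$brain$values, h$brain$dt, window)
    ap <- element_peaks(h$axonal$values, h$axonal$dt, window)
    bw <- h$brain$weights
    out <- data.frame(
      subject_id = id,
      MPS = percentile95(bp$peak_strain),
      MPSR = percentile95(bp$peak_rate),
      MPSxSR = percentile95(bp$peak_sxsr),
      MAS = percentile95(ap$peak_strain),
      MASR = percentile95(ap$peak_rate),
      MASxSR = percentile95(ap$peak_sxsr)
    )
    bf <- c(
      fraction_exceeding(bp$peak_strain, cutoffs$MPS, bw),
      fraction_exceeding(bp$peak_rate, cutoffs$MPSR, bw),
      fraction_exceeding(bp$peak_sxsr, cutoffs$MPSxSR, bw)
    )
    af <- c(
      fraction_exceeding(ap$peak_strain, cutoffs$MAS),
      fraction_exceeding(ap$peak_rate, cutoffs$MASR),
      fraction_exceeding(ap$peak_sxsr, cutoffs$MASxSR)
    )
    fnames <- c(frac_name("BF", "MPS"), frac_name("BF", "MPSR"),
                frac_name("BF", "MPSxSR"), frac_name("AF", "MAS"),
                frac_name("AF", "MASR"), frac_name("AF", "MASxSR"))
    out[fnames] <- as.list(100 * c(bf, af))
    dvf <- c(dvf_from_fraction(bf, "brain"),
             dvf_from_fraction(af, "axonal", gamma_v))
    out[paste0("DVF_", c("MPS", "MPSR", "MPSxSR", "MAS", "MASR", "MASxSR"))] <-
      as.list(100 * dvf)
    out
  })
  missing <- subject_ids[vapply(rows, is.null, TRUE)]
  if (length(missing)) {
    warning("skipping subjects with missing histories: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
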