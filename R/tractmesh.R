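# Conversion of tractography streamlines (polylines with per-point FA) into
# 1-mm cable-element sets with FA-based material grouping.

#' Reference FA-group frequency distribution
#'
#' The eight fractional-anisotropy bins used to group axonal cable elements
#' for material assignment, with the reference percentage frequency of
#' elements per bin observed in a piglet whole-brain tractogram. Bins are
#' half-open `[lo, hi)`; the last bin is closed.
#'
#' @return A data frame with columns `group`, `fa_lo`, `fa_hi`, `percent`.
#' @export
fa_reference_distribution <- function() {
  data.frame(
    group = 1:8,
    fa_lo = seq(0.2, 0.9, by = 0.1),
    fa_hi = c(seq(0.3, 0.9, by = 0.1), 1.0),
    percent = c(2.02, 23.78, 30.55, 22.83, 13.76, 5.11, 1.41, 0.52)
  )
}

#' Read streamlines from a plain-text polyline file
#'
#' One streamline per block; each line holds `x y z fa` (mm and
#' dimensionless FA); blocks are separated by blank lines.
#'
#' @param path Path to the file.
#' @return A list of data frames with columns `x`, `y`, `z`, `fa`.
#' @export
read_streamlines <- function(path) {
  lines <- readLines(path)
  blank <- grepl("^\\s*$", lines)
  block <- cumsum(blank)[!blank]
  lines <- lines[!blank]
  lapply(split(lines, block), function(b) {
    m <- do.call(rbind, lapply(strsplit(trimws(b), "\\s+"), as.numeric))
    stats::setNames(as.data.frame(m), c("x", "y", "z", "fa"))
  })
}

#' Write streamlines to the plain-text polyline format
#'
#' @param streamlines List of data frames with columns `x`, `y`, `z`, `fa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(streamlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in streamlines) {
    writeLines(sprintf("%.6f %.6f %.6f %.6f", s$x, s$y, s$z, s$fa), con)
    writeLines("", con)
  }
  invisible(path)
}

.validate_streamline <- function(s) {
  stopifnot(all(c("x", "y", "z", "fa") %in% names(s)), nrow(s) >= 2,
            all(is.finite(as.matrix(s[c("x", "y", "z")]))),
            all(s$fa >= 0 & s$fa <= 1))
}

#' Discretize streamlines into equal-length cable elements
#'
#' Each streamline is re-sampled along its arclength into
#' `round(arclength / target_length)` elements (minimum one) of equal actual
#' length, so total arclength is preserved. Each element receives the
#' arithmetic mean of the FA samples of the seed points lying on its span
#' (endpoints inclusive); spans containing no sample fall back to the
#' nearest sample. Streamlines shorter than `target_length / 2` are skipped.
#'
#' @param streamlines List of data frames with columns `x`, `y`, `z`, `fa`.
#' @param target_length Nominal element length in mm (default 1).
#' @return A list of class `cable_element_set` with `elements` (data frame:
#'   `streamline`, `element`, `length`, `mean_fa`), `nodes` (data frame:
#'   `streamline`, `node`, `x`, `y`, `z`), and counts `n_skipped`,
#'   `n_fa_fallback`.
#' @export
discretize_streamlines <- function(streamlines, target_length = 1) {
  stopifnot(target_length > 0)
  elem_list <- list()
  node_list <- list()
  n_skipped <- 0L
  n_fallback <- 0L
  for (si in seq_along(streamlines)) {
    s <- streamlines[[si]]
    .validate_streamline(s)
    pts <- as.matrix(s[c("x", "y", "z")])
    seg <- sqrt(rowSums(diff(pts)^2))
    arc <- c(0, cumsum(seg))
    L <- arc[length(arc)]
    if (L < target_length / 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_el <- max(1L, round(L / target_length))
    elen <- L / n_el
    node_s <- seq(0, L, length.out = n_el + 1)
    node_xyz <- vapply(seq_len(3), function(d) {
      stats::approx(arc, pts[, d], xout = node_s, ties = "ordered")$y
    }, numeric(n_el + 1))
    mean_fa <- numeric(n_el)
    for (e in seq_len(n_el)) {
      lo <- (e - 1) * elen
      hi <- e * elen
      in_span <- arc >= lo - 1e-9 & arc <= hi + 1e-9
      if (any(in_span)) {
        mean_fa[e] <- mean(s$fa[in_span])
      } else {
        n_fallback <- n_fallback + 1L
        mid <- (lo + hi) / 2
        mean_fa[e] <- s$fa[which.min(abs(arc - mid))]
      }
    }
    elem_list[[length(elem_list) + 1L]] <- data.frame(
      streamline = si, element = seq_len(n_el), length = elen, mean_fa = mean_fa
    )
    node_list[[length(node_list) + 1L]] <- data.frame(
      streamline = si, node = seq_len(n_el + 1),
      x = node_xyz[, 1], y = node_xyz[, 2], z = node_xyz[, 3]
    )
  }
  structure(
    list(
      elements = if (length(elem_list)) do.call(rbind, elem_list) else
        data.frame(streamline = integer(), element = integer(),
                   length = numeric(), mean_fa = numeric()),
      nodes = if (length(node_list)) do.call(rbind, node_list) else NULL,
      n_skipped = n_skipped, n_fa_fallback = n_fallback
    ),
    class = "cable_element_set"
  )
}

#' Group cable elements by fractional anisotropy
#'
#' Assigns each element to one of eight FA bins (`[0.2, 0.3)` ... `[0.9, 1]`;
#' half-open with the last bin closed) and tabulates the percentage
#' frequency per bin. Elements with FA below 0.2 fall under the tractography
#' tracking threshold: they are retained with `group = NA` and
#' `flagged = TRUE`, and excluded from the frequency table.
#'
#' @param x A `cable_element_set` from [discretize_streamlines()], or a
#'   numeric vector of mean FA values.
#' @return A list with `groups` (data frame: `mean_fa`, `group`, `flagged`)
#'   and `freq` (the [fa_reference_distribution()]-shaped frequency table
#'   with columns `group`, `fa_lo`, `fa_hi`, `n`, `percent`).
#' @export
group_by_fa <- function(x) {
  fa <- if (inherits(x, "cable_element_set")) x$elements$mean_fa else x
  stopifnot(is.numeric(fa), all(fa >= 0 & fa <= 1))
  edges <- seq(0.2, 1.0, by = 0.1)
  grp <- findInterval(fa, edges, rightmost.closed = TRUE)
  grp[grp == 0] <- NA_integer_
  flagged <- is.na(grp)
  bins <- fa_reference_distribution()[c("group", "fa_lo", "fa_hi")]
  n_in <- tabulate(grp, nbins = 8)
  bins$n <- n_in
  bins$percent <- if (sum(n_in) > 0) 100 * n_in / sum(n_in) else rep(0, 8)
  list(
    groups = data.frame(mean_fa = fa, group = grp, flagged = flagged),
    freq = bins
  )
}
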