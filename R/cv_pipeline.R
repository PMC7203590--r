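# Repeated stratified k-fold cross-validation of the risk analyses,
# fraction-metric cutoff optimization, and end-to-end orchestration.

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5, honoring the one-in-ten rule for a
#'   13/29 cohort).
#' @param repetitions Number of CV repetitions (default 50; data are
#'   reshuffled, re-stratified and re-partitioned before each).
#' @param seed Master seed; per-repetition seeds are spawned from it
#'   deterministically.
#' @param analyses Which risk analyses to run per iteration: any of
#'   `"blr"`, `"weibull"`, `"roc"`.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(k = 5L, repetitions = 50L, seed = 1L,
                      analyses = c("blr", "weibull", "roc")) {
  stopifnot(k >= 2, repetitions >= 1)
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(k = k, repetitions = repetitions, seed = seed,
                 analyses = analyses),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Partitions indices into `k` folds so that fold sizes differ by at most
#' one both overall and within each label class. Classes are dealt
#' round-robin from a shuffled order; later classes fill the currently
#' smallest folds first.
#'
#' @param labels Binary (or categorical) class labels.
#' @param k Number of folds; must not exceed the size of any class.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per index.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class must have at least `k` members", call. = FALSE)
  }
  .with_seed(seed, {
    fold <- integer(n)
    fold_sizes <- integer(k)
    classes <- names(sort(counts, decreasing = TRUE))
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      # deal into folds ordered by current load (random tie-break via the
      # preceding sample())
      target <- rep(order(fold_sizes, sample.int(k)), length.out = length(idx))
      fold[idx] <- target
      fold_sizes <- fold_sizes + tabulate(target, k)
    }
    fold
  })
}

.cv_iteration <- function(x, y, train, test, analyses) {
  out <- list()
  xr <- x[train]
  yr <- y[train]
  xt <- x[test]
  yt <- y[test]
  if ("roc" %in% analyses) {
    roc <- roc_curve(xr, yr)
    th <- optimal_roc_threshold(roc)
    sc <- classify_and_score(xt, yt, th)
    out <- c(out, list(auroc = roc$auroc, th_roc = th,
                       PAR_roc = sc$PAR, S_roc = sc$S, SP_roc = sc$SP))
  }
  if ("blr" %in% analyses) {
    fit <- fit_blr(xr, yr)
    th <- threshold_50(fit)
    sc <- classify_and_score(xt, yt, th)
    out <- c(out, list(r2_blr = fit$r2_adj, th_blr = th,
                       PAR_blr = sc$PAR, S_blr = sc$S, SP_blr = sc$SP))
  }
  if ("weibull" %in% analyses) {
    fit <- fit_weibull(xr, yr)
    th <- threshold_50(fit)
    sc <- classify_and_score(xt, yt, th)
    out <- c(out, list(aic_weibull = fit$aic, th_weibull = th,
                       PAR_weibull = sc$PAR, S_weibull = sc$S, SP_weibull = sc$SP))
  }
  out
}

#' Repeated stratified k-fold cross-validation of the risk analyses
#'
#' For each repetition the data are reshuffled, re-stratified and
#' partitioned into `k` folds; each fold in turn is held out while the
#' selected risk analyses (logistic, censored Weibull, ROC) are fitted on
#' the remaining folds. Thresholds extracted from the training folds (the
#' optimal-ROC threshold and the 50%-risk thresholds) are applied unchanged
#' to the held-out fold, and sensitivity, specificity and overall accuracy
#' are recorded per iteration, then aggregated as mean and SD over all
#' `k x repetitions` iterations. Iterations whose training folds contain a
#' single class are skipped and counted.
#'
#' @param x Per-subject metric values.
#' @param y Binary labels (1 = injured).
#' @param config A [cv_config()].
#' @return A list of class `cv_summary` with `iterations` (one row per
#'   iteration), `summary` (mean and SD per recorded quantity),
#'   `fold_assignments` (subjects x repetitions matrix), `n_skipped`,
#'   `train_fraction_range`.
#' @export
run_repeated_cv <- function(x, y, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"), length(x) == length(y))
  y <- .check_two_classes(y)
  n <- length(x)
  rep_seeds <- .spawn_seeds(config$seed, config$repetitions)
  assignments <- matrix(NA_integer_, n, config$repetitions)
  records <- list()
  n_skipped <- 0L
  train_sizes <- integer(0)
  for (r in seq_len(config$repetitions)) {
    fold <- stratified_folds(y, config$k, rep_seeds[r])
    assignments[, r] <- fold
    for (f in seq_len(config$k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(unique(y[train])) < 2 || length(test) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      rec <- .cv_iteration(x, y, train, test, config$analyses)
      records[[length(records) + 1L]] <-
        c(list(repetition = r, fold = f, n_train = length(train),
               n_test = length(test)), rec)
      train_sizes <- c(train_sizes, length(train))
    }
  }
  iterations <- do.call(rbind, lapply(records, as.data.frame))
  num_cols <- setdiff(names(iterations), c("repetition", "fold", "n_train", "n_test"))
  summary <- data.frame(
    quantity = num_cols,
    mean = vapply(num_cols, function(cn) mean(iterations[[cn]]), 0),
    sd = vapply(num_cols, function(cn) stats::sd(iterations[[cn]]), 0),
    row.names = NULL
  )
  structure(
    list(iterations = iterations, summary = summary,
         fold_assignments = assignments, n_skipped = n_skipped,
         train_fraction_range = range(train_sizes) / n),
    class = "cv_summary"
  )
}

#' Optimize a fraction-metric cutoff by cross-validated accuracy
#'
#' For each candidate cutoff, converts per-subject element peaks into the
#' exceedance-fraction metric, runs the (ROC-based) repeated CV, and records
#' the mean cross-validated accuracy (PAR) and AUROC. The selected cutoff
#' maximizes mean PAR; ties are broken by higher AUROC, then by the larger
#' cutoff (which predicts the smaller damaged volume).
#'
#' @param peaks_by_subject List (one entry per subject) of numeric vectors
#'   of per-element peaks.
#' @param y Binary labels (1 = injured).
#' @param grid Candidate cutoff values (nonempty).
#' @param config A [cv_config()]; only the ROC analysis is needed.
#' @param weights_by_subject Optional list of element weights (volumes) per
#'   subject.
#' @return A list with `optimal_cutoff` and `profile` (data frame: `cutoff`,
#'   `mean_PAR`, `mean_AUROC`).
#' @export
optimize_cutoff <- function(peaks_by_subject, y, grid,
                            config = cv_config(analyses = "roc"),
                            weights_by_subject = NULL) {
  stopifnot(length(grid) >= 1, length(peaks_by_subject) == length(y))
  profile <- lapply(grid, function(cutoff) {
    frac <- vapply(seq_along(peaks_by_subject), function(i) {
      fraction_exceeding(peaks_by_subject[[i]], cutoff,
                         weights_by_subject[[i]])
    }, 0)
    cv <- run_repeated_cv(frac, y, config)
    s <- cv$summary
    data.frame(cutoff = cutoff,
               mean_PAR = s$mean[s$quantity == "PAR_roc"],
               mean_AUROC = s$mean[s$quantity == "auroc"])
  })
  profile <- do.call(rbind, profile)
  ord <- order(-profile$mean_PAR, -profile$mean_AUROC, -profile$cutoff)
  list(optimal_cutoff = profile$cutoff[ord[1]], profile = profile)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end orchestration: generate (or accept) a cohort, generate element
#' strain histories per subject, compute the 12-metric table, optimize the
#' six fraction-metric cutoffs by cross-validated accuracy, run the repeated
#' CV with all three risk analyses for all 12 metrics, and assemble summary
#' tables (mean and SD of accuracy, sensitivity, specificity, fit quality
#' and thresholds per metric) plus a DVF-vs-AIV comparison by injury group.
#' Fully determined by `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @param cv A [cv_config()] for the 12-metric analysis.
#' @param cutoff_grids Named list of cutoff grids as in
#'   [default_cutoff_grids()]; set to `NULL` to skip cutoff optimization and
#'   use [default_cutoffs()].
#' @param cutoff_cv A [cv_config()] used inside the cutoff sweep (ROC only;
#'   fewer repetitions by default to bound runtime).
#' @return A list of class `tai_pipeline` with `cohort`, `metrics` (the
#'   12-metric table), `cutoffs`, `cutoff_profiles`, `cv_tables` (one
#'   summary data frame per analysis: `blr`, `roc`, `weibull`),
#'   `dvf_comparison`, and the `seed`/configs used.
#' @export
run_full_pipeline <- function(config = cohort_config(), seed = 1L,
                              cv = cv_config(seed = seed),
                              cutoff_grids = default_cutoff_grids(),
                              cutoff_cv = cv_config(repetitions = 10L,
                                                    seed = seed,
                                                    analyses = "roc")) {
  seeds <- .spawn_seeds(seed, 2L)
  cohort <- gen_cohort(config, seed = seeds[1])
  n <- nrow(cohort)
  subj_seeds <- .spawn_seeds(seeds[2], n)

  peaks <- vector("list", n)
  for (i in seq_len(n)) {
    h <- gen_element_histories(cohort[i, ], config, seed = subj_seeds[i])
    bp <- element_peaks(h$brain$values, h$brain$dt)
    ap <- element_peaks(h$axonal$values, h$axonal$dt)
    peaks[[i]] <- list(brain = bp, axonal = ap, brain_weights = h$brain$weights)
    rm(h)
  }
  y <- cohort$injured

  peak_col <- c(MPS = "peak_strain", MPSR = "peak_rate", MPSxSR = "peak_sxsr",
                MAS = "peak_strain", MASR = "peak_rate", MASxSR = "peak_sxsr")
  src <- c(MPS = "brain", MPSR = "brain", MPSxSR = "brain",
           MAS = "axonal", MASR = "axonal", MASxSR = "axonal")

  cutoffs <- default_cutoffs()
  cutoff_profiles <- NULL
  if (!is.null(cutoff_grids)) {
    cutoff_profiles <- list()
    for (m in names(cutoff_grids)) {
      pk <- lapply(peaks, function(p) p[[src[m]]][[peak_col[m]]])
      wt <- if (src[m] == "brain") lapply(peaks, `[[`, "brain_weights") else NULL
      opt <- optimize_cutoff(pk, y, cutoff_grids[[m]], cutoff_cv, wt)
      cutoffs[[m]] <- opt$optimal_cutoff
      cutoff_profiles[[m]] <- opt$profile
    }
  }

  # 12-metric per-subject table at the (optimized) cutoffs
  metric_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- peaks[[i]]
    row <- data.frame(
      subject_id = cohort$subject_id[i],
      MPS = percentile95(p$brain$peak_strain),
      MPSR = percentile95(p$brain$peak_rate),
      MPSxSR = percentile95(p$brain$peak_sxsr),
      MAS = percentile95(p$axonal$peak_strain),
      MASR = percentile95(p$axonal$peak_rate),
      MASxSR = percentile95(p$axonal$peak_sxsr),
      BF_MPS = 100 * fraction_exceeding(p$brain$peak_strain, cutoffs$MPS, p$brain_weights),
      BF_MPSR = 100 * fraction_exceeding(p$brain$peak_rate, cutoffs$MPSR, p$brain_weights),
      BF_MPSxSR = 100 * fraction_exceeding(p$brain$peak_sxsr, cutoffs$MPSxSR, p$brain_weights),
      AF_MAS = 100 * fraction_exceeding(p$axonal$peak_strain, cutoffs$MAS),
      AF_MASR = 100 * fraction_exceeding(p$axonal$peak_rate, cutoffs$MASR),
      AF_MASxSR = 100 * fraction_exceeding(p$axonal$peak_sxsr, cutoffs$MASxSR)
    )
    row
  }))

  metric_names <- setdiff(names(metric_tab), "subject_id")
  cv_results <- lapply(metric_names, function(m) {
    run_repeated_cv(metric_tab[[m]], y, cv)
  })
  names(cv_results) <- metric_names

  pull <- function(quantity) {
    vapply(cv_results, function(r) {
      s <- r$summary
      i <- match(quantity, s$quantity)
      c(mean = s$mean[i], sd = s$sd[i])
    }, c(mean = 0, sd = 0))
  }
  mk_table <- function(quantities) {
    out <- data.frame(metric = metric_names)
    for (q in quantities) {
      v <- pull(q)
      out[[paste0(q, "_mean")]] <- v["mean", ]
      out[[paste0(q, "_sd")]] <- v["sd", ]
    }
    out
  }
  cv_tables <- list()
  if ("blr" %in% cv$analyses) {
    cv_tables$blr <- mk_table(c("PAR_blr", "S_blr", "SP_blr", "r2_blr", "th_blr"))
  }
  if ("roc" %in% cv$analyses) {
    cv_tables$roc <- mk_table(c("PAR_roc", "S_roc", "SP_roc", "auroc", "th_roc"))
  }
  if ("weibull" %in% cv$analyses) {
    cv_tables$weibull <- mk_table(c("PAR_weibull", "S_weibull", "SP_weibull",
                                    "aic_weibull", "th_weibull"))
  }

  # DVF estimates (percent of whole-brain volume) vs AIV, by injury group
  dvf <- data.frame(
    subject_id = cohort$subject_id,
    injured = y,
    AIV = cohort$aiv_percent,
    DVF_MPS = metric_tab$BF_MPS,
    DVF_MPSR = metric_tab$BF_MPSR,
    DVF_MPSxSR = metric_tab$BF_MPSxSR,
    DVF_MAS = dvf_from_fraction(metric_tab$AF_MAS, "axonal"),
    DVF_MASR = dvf_from_fraction(metric_tab$AF_MASR, "axonal"),
    DVF_MASxSR = dvf_from_fraction(metric_tab$AF_MASxSR, "axonal")
  )
  grp_means <- stats::aggregate(dvf[setdiff(names(dvf), c("subject_id", "injured"))],
                                by = list(injured = dvf$injured), FUN = mean)

  structure(
    list(cohort = cohort, metrics = metric_tab, cutoffs = cutoffs,
         cutoff_profiles = cutoff_profiles, cv_tables = cv_tables,
         cv_results = cv_results, dvf_comparison = dvf,
         dvf_group_means = grp_means,
         seed = seed, config = config, cv = cv),
    class = "tai_pipeline"
  )
}
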