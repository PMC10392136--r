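#' Filter features by missing-value rate
#'
#' Removes features whose missing fraction is strictly greater than
#' `max_missing_fraction` (so "over 90% missing" removes at > 0.9 and a
#' feature at exactly 0.9 is retained). Feature order is preserved.
#'
#' @param m an [omics_matrix()] (intensity layer).
#' @param max_missing_fraction maximum tolerated per-feature missing
#'   fraction.
#' @return the filtered [omics_matrix()].
#' @export
filter_features_by_missing <- function(m, max_missing_fraction = 0.9) {
  frac <- rowMeans(is.na(m$values))
  subset_omics(m, features = which(frac <= max_missing_fraction))
}

#' Flag outlier samples by identification count
#'
#' Samples with extremely low numbers of quantified proteins are flagged
#' by a robust z-score on the per-sample non-missing feature count:
#' a sample is an outlier if its count lies more than `z_threshold`
#' MAD-scaled deviations below the median count.
#'
#' @param m an [omics_matrix()] with at least 3 samples.
#' @param z_threshold robust z cutoff.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(m, z_threshold = 3) {
  if (ncol(m$values) < 3L) stop("need at least 3 samples")
  counts <- colSums(!is.na(m$values))
  dev <- counts - stats::median(counts)
  z <- dev / stats::mad(counts)       # +-Inf when MAD = 0 and dev != 0
  flagged <- !is.nan(z) & z < -z_threshold
  names(counts)[flagged]
}

#' Pairwise replicate correlations
#'
#' Pearson correlation on pairwise-complete log2 values for every sample
#' pair, labeled `technical` (same cell line, replicate groups 3 vs 4 --
#' group 4 is the technical re-measurement of biological replicate 3),
#' `biological` (same cell line otherwise) or `non_replicate` (different
#' cell lines). Pairs with fewer than 3 co-observed features are skipped
#' and counted.
#'
#' @param m an [omics_matrix()].
#' @param ann a [sample_annotation()] covering all samples of `m`.
#' @return list of class `replicate_correlations` with elements `pairs`
#'   (data.frame sample_a, sample_b, label, r, n_obs), `medians` (named
#'   vector, `NA` for labels with no usable pair) and `n_skipped`.
#' @export
replicate_correlations <- function(m, ann) {
  a <- join_annotation(m, ann)
  v <- m$values
  n <- ncol(v)
  if (n < 2L) stop("need at least 2 samples")
  r_all <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  n_co <- crossprod(!is.na(v))
  idx <- which(upper.tri(r_all), arr.ind = TRUE)
  same_line <- a$cell_line[idx[, 1L]] == a$cell_line[idx[, 2L]]
  g1 <- a$replicate_group[idx[, 1L]]; g2 <- a$replicate_group[idx[, 2L]]
  tech <- same_line & ((g1 == 3L & g2 == 4L) | (g1 == 4L & g2 == 3L))
  label <- ifelse(tech, "technical",
                  ifelse(same_line, "biological", "non_replicate"))
  pairs <- data.frame(sample_a = colnames(v)[idx[, 1L]],
                      sample_b = colnames(v)[idx[, 2L]],
                      label = label,
                      r = r_all[idx],
                      n_obs = n_co[idx])
  usable <- pairs$n_obs >= 3L & !is.na(pairs$r)
  n_skipped <- sum(!usable)
  pairs_used <- pairs[usable, , drop = FALSE]
  medians <- vapply(c("technical", "biological", "non_replicate"),
                    function(l) {
                      r <- pairs_used$r[pairs_used$label == l]
                      if (length(r)) stats::median(r) else NA_real_
                    }, numeric(1))
  structure(list(pairs = pairs_used, medians = medians,
                 n_skipped = n_skipped),
            class = "replicate_correlations")
}

#' @export
print.replicate_correlations <- function(x, ...) {
  cat("replicate correlations (median Pearson r):\n")
  for (l in names(x$medians))
    cat(sprintf("  %-13s %s  (%d pairs)\n", l,
                ifelse(is.na(x$medians[[l]]), "absent",
                       sprintf("%.3f", x$medians[[l]])),
                sum(x$pairs$label == l)))
  if (x$n_skipped) cat("  skipped pairs (<3 co-observed):", x$n_skipped, "\n")
  invisible(x)
}

#' Coefficient of variation by abundance level
#'
#' Per feature, the CV (sd/mean of linear-scale intensities) is computed
#' across each cell line's replicates and averaged over lines; features
#' are then binned by median log2 abundance into `n_bins` quantile bins
#' and the median CV per bin is reported. Features never observed in at
#' least two replicates of any line are excluded.
#'
#' @param m an [omics_matrix()] (replicate-level, log2).
#' @param ann a [sample_annotation()].
#' @param n_bins number of abundance quantile bins.
#' @return data.frame with columns `bin`, `abundance_lo`, `abundance_hi`,
#'   `median_cv`, `n_features`.
#' @export
cv_by_abundance <- function(m, ann, n_bins = 3) {
  a <- join_annotation(m, ann)
  v <- m$values
  cv_sum <- cv_cnt <- numeric(nrow(v))
  for (line in unique(a$cell_line)) {
    cols <- which(a$cell_line == line)
    if (length(cols) < 2L) next
    x <- 2^v[, cols, drop = FALSE]
    k <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums(x^2, na.rm = TRUE) - k * mu^2
    s <- sqrt(pmax(ss, 0) / (k - 1))
    ok <- k >= 2L
    cv_sum[ok] <- cv_sum[ok] + (s / mu)[ok]
    cv_cnt[ok] <- cv_cnt[ok] + 1L
  }
  keep <- cv_cnt > 0
  if (!any(keep)) stop("no feature observed in >=2 replicates of any line")
  cv <- cv_sum[keep] / cv_cnt[keep]
  ab <- apply(v[keep, , drop = FALSE], 1L, stats::median, na.rm = TRUE)
  br <- stats::quantile(ab, probs = seq(0, 1, length.out = n_bins + 1L))
  br[1L] <- -Inf
  bin <- cut(ab, br, labels = FALSE, include.lowest = TRUE)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    data.frame(bin = b,
               abundance_lo = if (b == 1L) min(ab) else unname(br[b]),
               abundance_hi = unname(br[b + 1L]),
               median_cv = stats::median(cv[bin == b]),
               n_features = sum(bin == b))
  }))
  out
}

#' Center out batch effects per feature
#'
#' Location-only batch adjustment: per feature, subtract the
#' batch-specific mean (over non-missing entries) and add back the grand
#' mean. The missing pattern is unchanged; a batch in which a feature is
#' entirely missing is left unadjusted for that feature; within-batch
#' variance is untouched.
#'
#' @param m an [omics_matrix()].
#' @param ann a [sample_annotation()].
#' @return the batch-centered [omics_matrix()].
#' @export
batch_center <- function(m, ann) {
  a <- join_annotation(m, ann)
  v <- m$values
  grand <- rowMeans(v, na.rm = TRUE)
  for (b in unique(a$batch)) {
    cols <- which(a$batch == b)
    bm <- rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
    adj <- grand - bm
    adj[is.nan(bm)] <- 0          # feature all-missing in this batch
    v[, cols] <- v[, cols, drop = FALSE] + adj
  }
  omics_matrix(v, m$layer_name)
}

#' Average replicates to a cell-line-level matrix
#'
#' One column per cell line: the mean of the non-missing replicate values
#' per feature. An entry is missing only if the feature is missing in all
#' replicates of that line.
#'
#' @param m an [omics_matrix()] (replicate-level).
#' @param ann a [sample_annotation()].
#' @return a cell-line-level [omics_matrix()] (columns named by cell
#'   line, in order of first appearance).
#' @export
average_replicates <- function(m, ann) {
  a <- join_annotation(m, ann)
  lines <- unique(a$cell_line)
  v <- vapply(lines, function(line) {
    x <- m$values[, a$cell_line == line, drop = FALSE]
    out <- rowMeans(x, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }, numeric(nrow(m$values)))
  v <- matrix(v, nrow(m$values), length(lines),
              dimnames = list(rownames(m$values), lines))
  omics_matrix(v, m$layer_name)
}

#' Run the full matrix-level QC stage
#'
#' Applies, in order: missing-rate feature filtering, outlier-sample
#' detection and removal, replicate-correlation and CV diagnostics,
#' batch centering and replicate averaging.
#'
#' @param m replicate-level [omics_matrix()].
#' @param ann a [sample_annotation()].
#' @param config a [run_config()].
#' @return list of class `qc_report`: counts before/after, missing
#'   fractions, removed outliers, replicate correlations, CV table, and
#'   the `filtered` (replicate-level, batch-centered) and `averaged`
#'   (cell-line-level) matrices.
#' @export
qc_pipeline <- function(m, ann, config = run_config()) {
  n_before <- nrow(m$values)
  miss_before <- missing_fraction(m)
  filt <- filter_features_by_missing(m, config$qc_max_missing_fraction)
  outliers <- detect_outlier_samples(filt, config$qc_outlier_z)
  if (length(outliers))
    filt <- subset_omics(filt, samples = setdiff(sample_ids(filt), outliers))
  rc <- replicate_correlations(filt, ann)
  cv <- cv_by_abundance(filt, ann, config$qc_cv_bins)
  centered <- if (length(unique(join_annotation(filt, ann)$batch)) > 1L)
    batch_center(filt, ann) else filt
  avg <- average_replicates(centered, ann)
  structure(list(n_features_before = n_before,
                 n_features_after = nrow(filt$values),
                 missing_before = miss_before,
                 missing_after = missing_fraction(filt),
                 removed_outliers = outliers,
                 replicate_correlations = rc,
                 cv_by_abundance = cv,
                 filtered = centered,
                 averaged = avg), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d features; missing %.1f%% -> %.1f%%\n",
              x$n_features_before, x$n_features_after,
              100 * x$missing_before, 100 * x$missing_after))
  if (length(x$removed_outliers))
    cat("removed outlier sample(s):",
        paste(x$removed_outliers, collapse = ", "), "\n")
  print(x$replicate_correlations)
  cat("median CV by abundance bin:",
      paste(sprintf("%.3f", x$cv_by_abundance$median_cv), collapse = ", "),
      "\n")
  invisible(x)
}
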