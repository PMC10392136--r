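#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending, the adjusted
#' value at rank i is `min_{j >= i} p_(j) * n / j`, capped at 1, and
#' results are returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}

# vectorized two-sample t test over matrix rows (log2 values).
# equal_variance = TRUE gives the pooled-variance Student test, FALSE
# the Welch test. Rows with fewer than 2 observations in either group
# are returned untested (NA). A zero-variance row with zero mean
# difference gets t = 0, p = 1; with nonzero difference, p = 0.
row_t_stats <- function(v, in_g1, equal_variance = TRUE) {
  x1 <- v[, in_g1, drop = FALSE]; x2 <- v[, !in_g1, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  s1 <- (rowSums(x1^2, na.rm = TRUE) - n1 * m1^2) / (n1 - 1)
  s2 <- (rowSums(x2^2, na.rm = TRUE) - n2 * m2^2) / (n2 - 1)
  s1 <- pmax(s1, 0); s2 <- pmax(s2, 0)
  tested <- n1 >= 2 & n2 >= 2
  if (equal_variance) {
    sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(s1 / n1 + s2 / n2)
    df <- (s1 / n1 + s2 / n2)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  }
  diff <- m1 - m2
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_se <- tested & se == 0
  t[zero_se & diff == 0] <- 0; p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0
  t[!tested] <- NA_real_; p[!tested] <- NA_real_
  list(mean1 = m1, mean2 = m2, t = t, p = p, tested = tested,
       n1 = n1, n2 = n2)
}

#' TNBC vs non-TNBC differential expression
#'
#' Per-feature two-tailed unpaired t test on log2 values (equal-variance
#' Student by default), fold change from the difference of group means
#' on the log2 scale (geometric-mean ratio), Benjamini-Hochberg
#' adjustment across all tested features, and a DEP flag at joint
#' adjusted-p and fold-change thresholds. A feature with fewer than two
#' non-missing values in either group is reported untested and excluded
#' from the B-H family.
#'
#' @param m an [omics_matrix()] (typically cell-line-averaged).
#' @param group1 logical vector (aligned to the columns of `m`) marking
#'   group 1 (e.g. TNBC).
#' @param p_threshold adjusted-p cutoff for the DEP flag.
#' @param fc_up,fc_down linear fold-change cutoffs (DEP when fold change
#'   `> fc_up` or `< fc_down`).
#' @param equal_variance pooled-variance Student test (`TRUE`, default)
#'   or Welch (`FALSE`).
#' @return data.frame of class `dep_table`: `feature_id`,
#'   `mean_log2_group1`, `mean_log2_group2`, `log2_fold_change`,
#'   `fold_change`, `p_value`, `adjusted_p`, `tested`, `is_dep`.
#' @export
differential_expression <- function(m, group1, p_threshold = 0.05,
                                    fc_up = 1.5, fc_down = 0.67,
                                    equal_variance = TRUE) {
  if (length(group1) != ncol(m$values))
    stop("'group1' must have one entry per sample")
  if (!any(group1) || all(group1)) stop("both groups must be non-empty")
  st <- row_t_stats(m$values, group1, equal_variance)
  lfc <- st$mean1 - st$mean2
  fc <- 2^lfc
  adj <- rep(NA_real_, length(st$p))
  adj[st$tested] <- bh_adjust(st$p[st$tested])
  is_dep <- !is.na(adj) & adj < p_threshold & (fc > fc_up | fc < fc_down)
  structure(data.frame(feature_id = feature_ids(m),
                       mean_log2_group1 = st$mean1,
                       mean_log2_group2 = st$mean2,
                       log2_fold_change = lfc,
                       fold_change = fc,
                       p_value = st$p,
                       adjusted_p = adj,
                       tested = st$tested,
                       is_dep = is_dep,
                       row.names = NULL),
            class = c("dep_table", "data.frame"))
}

#' Select the most significant differentially expressed features
#'
#' The `n` DEPs with the smallest adjusted p; ties are broken by larger
#' absolute log2 fold change, then by feature id.
#'
#' @param dep a [differential_expression()] table.
#' @param n signature size.
#' @return character vector of feature ids (shorter than `n`, with a
#'   warning, if fewer DEPs exist).
#' @export
select_signature <- function(dep, n = 38) {
  d <- dep[dep$is_dep, , drop = FALSE]
  if (nrow(d) < n)
    warning(sprintf("only %d DEPs available; returning all", nrow(d)))
  ord <- order(d$adjusted_p, -abs(d$log2_fold_change), d$feature_id)
  d$feature_id[ord][seq_len(min(n, nrow(d)))]
}

#' Silhouette separation of a signature
#'
#' Mean silhouette width of the TNBC / non-TNBC labels in the signature
#' subspace, using correlation distance between samples over
#' complete-case signature features. Scores near 1 mean the signature
#' cleanly separates the two groups; scores near 0 mean no structure.
#'
#' @param m an [omics_matrix()] (cell-line level).
#' @param ann a [sample_annotation()] providing the `tnbc` label.
#' @param signature character vector of >= 2 feature ids present in `m`.
#' @return mean silhouette width in \[-1, 1\].
#' @export
signature_separation <- function(m, ann, signature) {
  if (length(signature) < 2L) stop("signature must contain >= 2 features")
  absent <- setdiff(signature, feature_ids(m))
  if (length(absent))
    stop("signature feature(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  a <- join_annotation(m, ann)
  v <- m$values[signature, , drop = FALSE]
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) < 2L) stop("fewer than 2 complete-case signature features")
  d <- stats::as.dist(1 - stats::cor(v))
  lab <- as.integer(a$tnbc) + 1L
  sil <- cluster::silhouette(lab, d)
  mean(sil[, "sil_width"])
}
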