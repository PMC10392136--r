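#' Enumerate within-complex subunit pairs present in a matrix
#'
#' All unordered member pairs of each complex whose two members are both
#' rows of the matrix. A complex is "matched" if it contributes at least
#' one pair; singleton complexes and complexes with fewer than two
#' measured members contribute none.
#'
#' @param cat a [complex_catalog()].
#' @param m an [omics_matrix()].
#' @return data.frame with columns `complex_id`, `feature_a`,
#'   `feature_b` (`feature_a < feature_b` lexicographically); the number
#'   of matched complexes is in attribute `n_matched`.
#' @export
enumerate_complex_pairs <- function(cat, m) {
  feats <- feature_ids(m)
  rows <- lapply(names(cat), function(id) {
    present <- sort(intersect(cat[[id]], feats))
    if (length(present) < 2L) return(NULL)
    cmb <- utils::combn(present, 2L)
    data.frame(complex_id = id, feature_a = cmb[1L, ], feature_b = cmb[2L, ])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(complex_id = character(), feature_a = character(),
                      feature_b = character())
  attr(out, "n_matched") <- length(unique(out$complex_id))
  out
}

#' Pearson correlation of subunit pairs
#'
#' Per pair, Pearson r across cell lines on pairwise-complete values of
#' the cell-line-averaged matrix. Pairs with fewer than `min_obs`
#' co-observed lines, or with a zero-variance member on the co-observed
#' lines, are dropped and counted.
#'
#' @param pairs output of [enumerate_complex_pairs()].
#' @param m cell-line-level [omics_matrix()].
#' @param level label recorded per row (`"protein"` or `"transcript"`).
#' @param min_obs minimum co-observed lines per pair.
#' @return data.frame of class `pair_correlation_table` with columns
#'   `complex_id`, `feature_a`, `feature_b`, `level`, `pearson_r`,
#'   `n_samples_used`; dropped-pair counts in attribute `n_dropped`.
#' @export
pair_correlations <- function(pairs, m, level = "protein", min_obs = 3) {
  v <- m$values
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- v[pairs$feature_a[i], ]; y <- v[pairs$feature_b[i], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_obs) return(list(r = NA_real_, n = sum(ok)))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(list(r = NA_real_, n = sum(ok)))
    list(r = stats::cor(x[ok], y[ok]), n = sum(ok))
  })
  out <- data.frame(pairs,
                    level = level,
                    pearson_r = vapply(res, `[[`, numeric(1), "r"),
                    n_samples_used = vapply(res, `[[`, numeric(1), "n"))
  dropped <- is.na(out$pearson_r)
  attr_n <- sum(dropped)
  out <- out[!dropped, , drop = FALSE]
  attr(out, "n_dropped") <- attr_n
  class(out) <- c("pair_correlation_table", "data.frame")
  out
}

#' Compare subunit co-expression between protein and transcript levels
#'
#' Two-tailed unpaired equal-variance Student's t test on the two lists
#' of pair correlations, with the median of each list.
#'
#' @param protein_rs,transcript_rs numeric vectors of pair correlations
#'   (each of length >= 2).
#' @return list with `t_statistic`, `p_value`, `median_protein`,
#'   `median_transcript`.
#' @export
compare_levels <- function(protein_rs, transcript_rs) {
  if (length(protein_rs) < 2L || length(transcript_rs) < 2L)
    stop("need at least 2 correlations per level")
  tt <- stats::t.test(protein_rs, transcript_rs, var.equal = TRUE)
  list(t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       median_protein = stats::median(protein_rs),
       median_transcript = stats::median(transcript_rs))
}

#' Top correlated subunit pairs
#'
#' The `n` pairs with the largest Pearson r at the given level; ties are
#' broken by (`complex_id`, `feature_a`, `feature_b`) lexicographic
#' order.
#'
#' @param table a [pair_correlations()] table.
#' @param n number of pairs to return.
#' @param level which level to rank (`NULL` keeps all rows).
#' @return the ranked head of the table.
#' @export
top_pairs <- function(table, n = 10, level = NULL) {
  if (!nrow(table)) stop("empty pair correlation table")
  if (!is.null(level)) table <- table[table$level == level, , drop = FALSE]
  ord <- order(-table$pearson_r, table$complex_id, table$feature_a,
               table$feature_b)
  out <- table[ord, , drop = FALSE][seq_len(min(n, nrow(table))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the protein-complex co-expression stage
#'
#' @param protein,transcript cell-line-level [omics_matrix()] objects.
#' @param cat a [complex_catalog()].
#' @param config a [run_config()].
#' @return list of class `complex_coexpression`: the combined pair
#'   table, matched complex counts, the protein vs transcript
#'   comparison, and the top pairs per level.
#' @export
complex_coexpression <- function(protein, transcript, cat,
                                 config = run_config()) {
  pp <- enumerate_complex_pairs(cat, protein)
  tp <- enumerate_complex_pairs(cat, transcript)
  prot_r <- pair_correlations(pp, protein, "protein", config$complex_min_obs)
  tx_r <- pair_correlations(tp, transcript, "transcript",
                            config$complex_min_obs)
  cmp <- compare_levels(prot_r$pearson_r, tx_r$pearson_r)
  tab <- rbind(as.data.frame(prot_r), as.data.frame(tx_r))
  class(tab) <- c("pair_correlation_table", "data.frame")
  structure(list(pairs = tab,
                 n_matched_protein = attr(pp, "n_matched"),
                 n_matched_transcript = attr(tp, "n_matched"),
                 comparison = cmp,
                 top_protein = top_pairs(prot_r, 10),
                 top_transcript = top_pairs(tx_r, 10)),
            class = "complex_coexpression")
}

#' @export
print.complex_coexpression <- function(x, ...) {
  cat(sprintf(
    "complex co-expression: %d matched complexes (protein level)\n",
    x$n_matched_protein))
  cat(sprintf("  median r: protein %.3f, transcript %.3f (t = %.2f, p = %.3g)\n",
              x$comparison$median_protein, x$comparison$median_transcript,
              x$comparison$t_statistic, x$comparison$p_value))
  invisible(x)
}
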