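#' k-nearest-neighbour imputation in feature space
#'
#' For each feature with missing entries, the `k` nearest features by
#' mean squared difference over co-observed samples supply the imputed
#' value as the mean of their (observed) values in the target sample.
#' Observed entries are unchanged. If no neighbour is observed in the
#' target sample, the feature's own mean over observed samples is used
#' as a last resort.
#'
#' @param m an [omics_matrix()]; every feature must have at least one
#'   observed value.
#' @param k number of neighbours.
#' @return a complete [omics_matrix()] with no missing entries.
#' @export
knn_impute <- function(m, k = 10) {
  v <- m$values
  if (!anyNA(v)) return(m)
  obs <- !is.na(v)
  none <- rowSums(obs) == 0L
  if (any(none))
    stop("feature(s) with zero observed values (filter first): ",
         paste(utils::head(rownames(v)[none], 5L), collapse = ", "))
  row_mean <- rowMeans(v, na.rm = TRUE)
  out <- v
  for (f in which(rowSums(!obs) > 0L)) {
    sq <- (v - rep(v[f, ], each = nrow(v)))^2   # NA where either missing
    msd <- rowMeans(sq, na.rm = TRUE)           # NaN with no shared sample
    msd[f] <- Inf
    msd[is.nan(msd)] <- Inf
    for (s in which(!obs[f, ])) {
      cand <- which(obs[, s] & is.finite(msd))
      if (!length(cand)) { out[f, s] <- row_mean[f]; next }
      nb <- cand[order(msd[cand], cand)][seq_len(min(k, length(cand)))]
      out[f, s] <- mean(v[nb, s])
    }
  }
  omics_matrix(out, m$layer_name)
}
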