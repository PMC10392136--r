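# vectorized pairwise-complete Pearson r of each matrix row against y
row_cor <- function(mat, y) {
  W <- !is.na(mat) & rep(!is.na(y), each = nrow(mat))
  m0 <- mat; m0[!W] <- 0
  ym <- matrix(y, nrow(mat), length(y), byrow = TRUE); ym[!W] <- 0
  n <- rowSums(W)
  sx <- rowSums(m0); sy <- rowSums(ym)
  sxx <- rowSums(m0^2); syy <- rowSums(ym^2); sxy <- rowSums(m0 * ym)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  r <- ifelse(n >= 3 & den > 0, num / sqrt(pmax(den, 0)), NA_real_)
  r
}

# vectorized one-way ANOVA over matrix rows; 'groups' indexes columns.
# Rows with <2 usable groups or no residual df get NA; a row with zero
# within- and between-group variance gets p = 1.
row_anova <- function(mat, groups) {
  gl <- unique(groups)
  G_n <- G_s <- G_ss <- vector("list", length(gl))
  for (i in seq_along(gl)) {
    x <- mat[, groups == gl[i], drop = FALSE]
    G_n[[i]] <- rowSums(!is.na(x))
    G_s[[i]] <- rowSums(x, na.rm = TRUE)
    G_ss[[i]] <- rowSums(x^2, na.rm = TRUE)
  }
  N <- Reduce(`+`, G_n)
  S <- Reduce(`+`, G_s)
  grand <- S / N
  G <- Reduce(`+`, lapply(G_n, function(n) as.integer(n > 0)))
  ssw <- ssb <- 0
  for (i in seq_along(gl)) {
    n <- G_n[[i]]; s <- G_s[[i]]
    mu <- ifelse(n > 0, s / n, 0)
    ssw <- ssw + ifelse(n > 0, G_ss[[i]] - n * mu^2, 0)
    ssb <- ssb + ifelse(n > 0, n * (mu - grand)^2, 0)
  }
  ssw <- pmax(ssw, 0)
  df1 <- G - 1L; df2 <- N - G
  FF <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(FF, df1, df2, lower.tail = FALSE)
  p[df1 < 1 | df2 < 1] <- NA_real_
  flat <- df1 >= 1 & df2 >= 1 & ssw == 0
  p[flat & ssb == 0] <- 1
  p[flat & ssb > 0] <- 0
  p
}

#' Summarize a time course to mean profiles
#'
#' Mean over non-missing replicates per (protein, cell line, drug, time
#' point); an entry is missing only if all replicates are missing.
#'
#' @param tc a [timecourse_experiment()].
#' @return list of class `profile_matrix`: `profiles` and `n_replicates`
#'   (4-d arrays protein x line x drug x time), `time_points_h`, `lines`,
#'   `tnbc` (named logical per line), `drugs`.
#' @export
summarize_timecourse <- function(tc) {
  s <- tc$samples
  lines <- unique(s$cell_line); drugs <- unique(s$drug)
  tp <- tc$time_points_h
  np <- nrow(tc$values)
  prof <- array(NA_real_, c(np, length(lines), length(drugs), length(tp)),
                dimnames = list(rownames(tc$values), lines, drugs, tp))
  nrep <- array(0L, dim(prof), dimnames = dimnames(prof))
  for (li in seq_along(lines)) for (di in seq_along(drugs))
    for (ti in seq_along(tp)) {
      cols <- which(s$cell_line == lines[li] & s$drug == drugs[di] &
                      s$time_h == tp[ti])
      x <- tc$values[, cols, drop = FALSE]
      mu <- rowMeans(x, na.rm = TRUE)
      mu[is.nan(mu)] <- NA_real_
      prof[, li, di, ti] <- mu
      nrep[, li, di, ti] <- rowSums(!is.na(x))
    }
  tnbc <- stats::setNames(s$tnbc[match(lines, s$cell_line)], lines)
  structure(list(profiles = prof, n_replicates = nrep,
                 time_points_h = tp, lines = lines, tnbc = tnbc,
                 drugs = drugs), class = "profile_matrix")
}

#' Screen proteins for correlation with drug IC50
#'
#' Per (drug, protein, time point): Pearson r across cell lines between
#' the mean expression profile and log10 IC50 (pairwise-complete). A
#' protein is eligible if fewer than `max_missing_timepoints + 1` time
#' points lack a computable r; eligible proteins are classified
#' `resistance_associated` when the mean r over computable time points
#' exceeds `tau`, `sensitivity_associated` when it is below `-tau`, else
#' `none`.
#'
#' @param profiles a [summarize_timecourse()] result.
#' @param response a [drug_response_table()] of log10 IC50.
#' @param tau absolute mean-correlation threshold.
#' @param max_missing_timepoints maximum tolerated non-computable time
#'   points per protein.
#' @return data.frame of class `ic50_screen`: `drug`, `protein`,
#'   `mean_r`, `n_timepoints_used`, `eligible`, `class`.
#' @export
ic50_screen <- function(profiles, response, tau = 0.7,
                        max_missing_timepoints = 1) {
  tp <- profiles$time_points_h
  out <- list()
  for (d in profiles$drugs) {
    ic50 <- response[match(profiles$lines, rownames(response)), d]
    if (sum(!is.na(ic50)) < 3L)
      stop("need >= 3 cell lines with response for drug ", d)
    rmat <- sapply(seq_along(tp), function(ti)
      row_cor(profiles$profiles[, , d, ti], ic50))
    n_ok <- rowSums(!is.na(rmat))
    eligible <- (length(tp) - n_ok) <= max_missing_timepoints & n_ok > 0
    mean_r <- rowMeans(rmat, na.rm = TRUE)
    mean_r[n_ok == 0] <- NA_real_
    cls <- rep("none", nrow(rmat))
    cls[eligible & !is.na(mean_r) & mean_r > tau] <- "resistance_associated"
    cls[eligible & !is.na(mean_r) & mean_r < -tau] <- "sensitivity_associated"
    out[[d]] <- data.frame(drug = d,
                           protein = rownames(profiles$profiles),
                           mean_r = mean_r,
                           n_timepoints_used = n_ok,
                           eligible = eligible,
                           class = cls)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ic50_screen", "data.frame")
  res
}

#' Fuzzy c-means clustering of z-scored profiles
#'
#' Standard alternating fuzzy c-means: memberships proportional to
#' `distance^(-2/(m-1))`, centroids the `membership^m`-weighted means,
#' iterated until the objective `sum_ij u_ij^m ||x_i - c_j||^2` changes
#' by less than `tol`. The objective is non-increasing; memberships per
#' profile sum to 1. Deterministic given the seed.
#'
#' @param x numeric matrix of complete, z-scored profiles (rows =
#'   proteins, columns = time points).
#' @param c number of clusters (>= 1).
#' @param m fuzzifier (> 1); as m approaches 1 the clustering hardens.
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed integer seed for the random membership initialization.
#' @return list of class `fuzzy_clustering`: `centroids` (c x T),
#'   `membership` (n x c), `m`, `objective` (per-iteration trace),
#'   `iterations`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2.0, tol = 1e-6, max_iter = 1000L,
                         seed = 1L) {
  stopifnot(is.matrix(x), !anyNA(x), c >= 1, m > 1)
  n <- nrow(x)
  if (c == 1L) {
    cent <- matrix(colMeans(x), 1L, ncol(x),
                   dimnames = list(NULL, colnames(x)))
    d2 <- rowSums((x - rep(cent, each = n))^2)
    return(structure(list(centroids = cent,
                          membership = matrix(1, n, 1,
                                              dimnames = list(rownames(x), NULL)),
                          m = m, objective = sum(d2), iterations = 1L),
                     class = "fuzzy_clustering"))
  }
  set.seed(seed)
  u <- matrix(stats::runif(n * c), n, c)
  u <- u / rowSums(u)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    cent <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rowSums(cent^2), `+`) - 2 * x %*% t(cent)
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    if (it > 1L && abs(obj[it - 1L] - obj[it]) < tol) break
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-1 / (m - 1))
    u <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
  }
  structure(list(centroids = cent, membership = u, m = m,
                 objective = obj, iterations = length(obj)),
            class = "fuzzy_clustering")
}

#' Z-score profiles over time, excluding flat profiles
#'
#' @param x numeric matrix (rows = profiles). Rows with missing entries
#'   or zero variance over time cannot be z-scored and are excluded.
#' @return list with `z` (z-scored matrix) and `excluded` (row ids).
#' @export
zscore_profiles <- function(x) {
  ok <- stats::complete.cases(x) & apply(x, 1L, stats::sd) > 0
  z <- t(scale(t(x[ok, , drop = FALSE])))
  list(z = z, excluded = rownames(x)[!ok])
}

#' Per-(protein, line, drug) time trend statistics
#'
#' One-way ANOVA of log2 replicate values across the time points, the
#' last-vs-first fold change `2^(mean_72h - mean_0h)`, and a direction
#' call gated on monotone consistency (Spearman |rho| of the mean
#' profile against time at least `monotone_rho`).
#'
#' @param tc a [timecourse_experiment()].
#' @param line,drug condition selectors.
#' @param proteins protein ids (default all).
#' @param monotone_rho Spearman threshold for a direction call.
#' @return data.frame: `protein`, `anova_p`, `log2_fc`, `fold_change`,
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
trend_stats <- function(tc, line, drug, proteins = rownames(tc$values),
                        monotone_rho = 0.8) {
  s <- tc$samples
  cols <- which(s$cell_line == line & s$drug == drug)
  if (!length(cols)) stop("no samples for this (line, drug)")
  v <- tc$values[proteins, cols, drop = FALSE]
  grp <- s$time_h[cols]
  p <- row_anova(v, grp)
  tp <- tc$time_points_h
  means <- sapply(tp, function(t) {
    mu <- rowMeans(v[, grp == t, drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    mu
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  lfc <- means[, ncol(means)] - means[, 1L]
  rho <- apply(means, 1L, function(mu) {
    ok <- !is.na(mu)
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(mu[ok], tp[ok], method = "spearman"))
  })
  dir <- ifelse(!is.na(rho) & abs(rho) >= monotone_rho & !is.na(lfc),
                ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
                "none")
  data.frame(protein = proteins, anova_p = p, log2_fc = lfc,
             fold_change = 2^lfc, direction = dir, row.names = NULL)
}

# per-(line, drug) direction calls for all proteins: a call requires
# B-H adjusted ANOVA p < anova_p (adjusted across proteins within the
# line/drug), |last/first fold change| beyond min_fc, and the monotone
# gate. Returns -1 / 0 / +1 per protein.
direction_calls <- function(tc, line, drug, anova_p = 0.05, min_fc = 2,
                            monotone_rho = 0.8) {
  ts <- trend_stats(tc, line, drug, monotone_rho = monotone_rho)
  adj <- rep(NA_real_, nrow(ts))
  ok <- !is.na(ts$anova_p)
  adj[ok] <- bh_adjust(ts$anova_p[ok])
  pass <- !is.na(adj) & adj < anova_p &
    !is.na(ts$log2_fc) & abs(ts$log2_fc) > log2(min_fc) &
    ts$direction != "none"
  ifelse(pass, ifelse(ts$direction == "up", 1L, -1L), 0L)
}

#' Select proteins with opposite dynamics in TNBC vs non-TNBC lines
#'
#' Per drug, a protein is selected when it has a consistent direction
#' (the same nonzero call in a strict majority of TNBC lines) and the
#' opposite consistent direction in a strict majority of non-TNBC
#' lines. A per-line call requires (i) B-H adjusted one-way ANOVA
#' p < `anova_p` over the time course and a monotone-consistent profile
#' and (ii) a last-vs-first fold change beyond `min_fc`. The final set
#' is the union over drugs with per-drug provenance, or the
#' intersection when `intersect_drugs` is set (the strict
#' "with every drug" reading).
#'
#' @param tc a [timecourse_experiment()].
#' @param config a [run_config()] (fields `dyn_anova_p`, `dyn_min_fc`,
#'   `dyn_monotone_rho`, `dyn_intersect_drugs`).
#' @return list of class `dynamics_selection`: `selected` (data.frame
#'   protein, drug, tnbc_direction), `proteins` (the de-duplicated id
#'   set), `calls` (protein x line x drug array of -1/0/+1).
#' @export
opposite_dynamics_select <- function(tc, config = run_config()) {
  s <- tc$samples
  lines <- unique(s$cell_line)
  tnbc <- s$tnbc[match(lines, s$cell_line)]
  if (!any(tnbc) || all(tnbc))
    stop("need both TNBC and non-TNBC lines")
  drugs <- unique(s$drug)
  prot <- rownames(tc$values)
  calls <- array(0L, c(length(prot), length(lines), length(drugs)),
                 dimnames = list(prot, lines, drugs))
  for (d in drugs) for (l in lines)
    calls[, l, d] <- direction_calls(tc, l, d, config$dyn_anova_p,
                                     config$dyn_min_fc,
                                     config$dyn_monotone_rho)
  sel_rows <- list()
  for (d in drugs) {
    cm <- calls[, , d, drop = FALSE][, , 1L]
    n_t <- sum(tnbc); n_n <- sum(!tnbc)
    up_t <- rowSums(cm[, tnbc, drop = FALSE] == 1L)
    dn_t <- rowSums(cm[, tnbc, drop = FALSE] == -1L)
    up_n <- rowSums(cm[, !tnbc, drop = FALSE] == 1L)
    dn_n <- rowSums(cm[, !tnbc, drop = FALSE] == -1L)
    # "consistent" = a strict majority of the group's lines call the
    # direction and no line in the group calls the opposite one; without
    # the no-contradiction clause, randomly relabeled groups would keep
    # majority opposition whenever the split is unbalanced
    opp_up <- up_t > n_t / 2 & dn_t == 0L & dn_n > n_n / 2 & up_n == 0L
    opp_dn <- dn_t > n_t / 2 & up_t == 0L & up_n > n_n / 2 & dn_n == 0L
    hit <- opp_up | opp_dn
    if (any(hit))
      sel_rows[[d]] <- data.frame(protein = prot[hit], drug = d,
                                  tnbc_direction = ifelse(opp_up[hit],
                                                          "up", "down"))
  }
  selected <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(protein = character(), drug = character(),
               tnbc_direction = character())
  rownames(selected) <- NULL
  proteins <- if (isTRUE(config$dyn_intersect_drugs)) {
    per_drug <- split(selected$protein, selected$drug)
    if (length(per_drug) < length(drugs)) character() else
      Reduce(intersect, per_drug)
  } else unique(selected$protein)
  structure(list(selected = selected, proteins = proteins, calls = calls,
                 tnbc = stats::setNames(tnbc, lines)),
            class = "dynamics_selection")
}

#' @export
print.dynamics_selection <- function(x, ...) {
  cat(sprintf("dynamics_selection: %d opposite-dynamics proteins (%d drug hits)\n",
              length(x$proteins), nrow(x$selected)))
  invisible(x)
}

#' Pathway-consistency filter for opposite-dynamics proteins
#'
#' A pathway passes when at least `ceil(tnbc_min * n_tnbc)` TNBC lines
#' and at least `ceil(non_tnbc_min * n_non)` non-TNBC lines each carry a
#' nonzero dysregulation call for at least one selected protein of the
#' pathway (thresholds inclusive).
#'
#' @param selection an [opposite_dynamics_select()] result.
#' @param pathways a [pathway_annotation()].
#' @param tnbc_min,non_tnbc_min required fractions of lines.
#' @return data.frame: `pathway`, `n_tnbc_lines`, `n_non_tnbc_lines`,
#'   `pass`.
#' @export
pathway_consistency <- function(selection, pathways,
                                tnbc_min = 3 / 5, non_tnbc_min = 2 / 4) {
  if (!length(pathways))
    return(data.frame(pathway = character(), n_tnbc_lines = integer(),
                      n_non_tnbc_lines = integer(), pass = logical()))
  tnbc <- selection$tnbc
  need_t <- ceiling(tnbc_min * sum(tnbc))
  need_n <- ceiling(non_tnbc_min * sum(!tnbc))
  sel <- selection$proteins
  # line is "hit" if any selected pathway member has a nonzero call
  # under any drug
  any_call <- apply(selection$calls != 0L, c(1L, 2L), any)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(intersect(pathways[[pw]], sel),
                         rownames(any_call))
    hit <- if (length(members))
      colSums(any_call[members, , drop = FALSE]) > 0 else
        stats::setNames(rep(FALSE, length(tnbc)), names(tnbc))
    nt <- sum(hit[tnbc]); nn <- sum(hit[!tnbc])
    data.frame(pathway = pw, n_tnbc_lines = nt, n_non_tnbc_lines = nn,
               pass = nt >= need_t & nn >= need_n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect persistently dysregulated proteins (PDPs)
#'
#' Per TNBC line, proteins differentially expressed between the 0 h and
#' 72 h replicates (two-tailed t test, B-H adjusted across proteins
#' within the line, joint fold-change thresholds). A PDP is a protein
#' that is a DEP in strictly more than `frac_threshold` of the TNBC
#' lines with usable endpoint data.
#'
#' @param tc a [timecourse_experiment()].
#' @param drug drug to analyse.
#' @param frac_threshold required fraction of TNBC lines (strict `>`).
#' @param p_threshold,fc_up,fc_down DEP thresholds.
#' @return character vector of PDP ids; attributes `n_lines_used` and
#'   `dep_counts` (per-protein DEP line counts).
#' @export
pdp_detect <- function(tc, drug, frac_threshold = 0.6,
                       p_threshold = 0.05, fc_up = 1.5, fc_down = 0.67) {
  s <- tc$samples
  t_last <- max(tc$time_points_h)
  lines <- unique(s$cell_line[s$tnbc])
  counts <- stats::setNames(integer(nrow(tc$values)), rownames(tc$values))
  used <- 0L
  for (l in lines) {
    c0 <- which(s$cell_line == l & s$drug == drug & s$time_h == 0)
    c1 <- which(s$cell_line == l & s$drug == drug & s$time_h == t_last)
    if (!length(c0) || !length(c1)) {
      warning("line ", l, " lacks baseline or endpoint data; excluded")
      next
    }
    used <- used + 1L
    v <- tc$values[, c(c1, c0), drop = FALSE]
    in_last <- seq_along(c(c1, c0)) <= length(c1)
    st <- row_t_stats(v, in_last)
    adj <- rep(NA_real_, length(st$p))
    adj[st$tested] <- bh_adjust(st$p[st$tested])
    fc <- 2^(st$mean1 - st$mean2)
    dep <- !is.na(adj) & adj < p_threshold & (fc > fc_up | fc < fc_down)
    counts <- counts + dep
  }
  if (!used) stop("no TNBC line with usable endpoint data")
  pdp <- names(counts)[counts > frac_threshold * used]
  attr(pdp, "n_lines_used") <- used
  attr(pdp, "dep_counts") <- counts
  pdp
}
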