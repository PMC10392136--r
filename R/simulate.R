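#' Specification of a synthetic multi-omics cohort
#'
#' Parameterizes [simulate_cohort()]. Defaults emulate the study
#' conditions of a 76-cell-line DIA breast cancer panel: 39 TNBC lines,
#' ~6000 proteins at ~34.7% intensity-dependent missingness, three
#' biological replicates plus one technical replicate of the third (run
#' in a separate batch), protein-mRNA coupling of r ~ 0.3,
#' complex-driven protein co-expression, and sparse linear drug-response
#' dependence on a handful of protein features per drug.
#'
#' @param n_cell_lines number of cell lines.
#' @param n_tnbc number of TNBC lines (must be <= `n_cell_lines`).
#' @param n_proteins,n_transcripts,n_mutations layer sizes. Transcripts
#'   are generated as cognates of the first `min(n_proteins,
#'   n_transcripts)` proteins so feature-wise protein-mRNA correlation is
#'   defined.
#' @param target_missing_fraction target fraction of missing cells in the
#'   replicate-level protein matrix, in \[0, 1).
#' @param protein_mrna_r target feature-wise Pearson correlation between
#'   line-level protein and transcript abundance.
#' @param n_complexes,complex_size_range synthetic complex catalog:
#'   number of complexes and range of member counts (members are disjoint
#'   across complexes).
#' @param complex_cor fraction of line-level protein variance carried by
#'   a shared per-complex latent factor (the within-complex correlation).
#' @param n_drugs number of drugs in the response table.
#' @param n_predictors_per_drug,predictor_beta,response_noise_sd sparse
#'   linear drug-response model: number of planted protein predictors per
#'   drug, their common effect size on standardized features, and the
#'   response noise sd.
#' @param response_missing_fraction fraction of (line, drug) responses
#'   left unscreened (missing completely at random).
#' @param bio_sd,tech_sd replicate noise sds on the log2 scale
#'   (`tech_sd` must not exceed `bio_sd`).
#' @param batch_offset additive log2 offset applied to replicate group 4
#'   (the technical replicate measured on a different instrument).
#' @param missing_slope scale (log2 units) of the logistic
#'   abundance-dependent missingness model.
#' @param seed integer random seed; the same spec and seed reproduce the
#'   cohort exactly.
#' @return a list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_cell_lines = 76L, n_tnbc = 39L,
                            n_proteins = 6000L, n_transcripts = n_proteins,
                            n_mutations = 123L,
                            target_missing_fraction = 0.347,
                            protein_mrna_r = 0.3,
                            n_complexes = 150L,
                            complex_size_range = c(2L, 6L),
                            complex_cor = 0.35,
                            n_drugs = 3L,
                            n_predictors_per_drug = 5L,
                            predictor_beta = 1,
                            response_noise_sd = 0.5,
                            response_missing_fraction = 0.1,
                            bio_sd = 0.2, tech_sd = 0.05,
                            batch_offset = 0.5,
                            missing_slope = 1.5,
                            seed = 1L) {
  spec <- as.list(environment())
  if (spec$target_missing_fraction < 0 || spec$target_missing_fraction >= 1)
    stop("target_missing_fraction must be in [0, 1)")
  if (spec$n_tnbc > spec$n_cell_lines)
    stop("n_tnbc cannot exceed n_cell_lines")
  if (spec$tech_sd > spec$bio_sd)
    stop("technical noise sd must not exceed biological noise sd")
  if (spec$protein_mrna_r >= 1)
    stop("infeasible protein-mRNA coupling: r must be < 1")
  if (spec$protein_mrna_r^2 + spec$complex_cor > 1)
    stop("infeasible variance budget: protein_mrna_r^2 + complex_cor > 1")
  structure(spec, class = "cohort_sim_spec")
}

# abundance-dependent (logistic) missingness: lower log2 abundance ->
# higher missing probability; intercept calibrated so the expected
# missing fraction equals the target.
apply_mnar_missing <- function(values, target, slope) {
  if (target <= 0) return(values)
  x <- as.vector(values)
  f <- function(c0) mean(stats::plogis(-(x - c0) / slope)) - target
  c0 <- stats::uniroot(f, range(x) + c(-50, 50))$root
  p <- stats::plogis(-(values - c0) / slope)
  u <- matrix(stats::runif(length(values)), nrow(values))
  values[u < p] <- NA_real_
  values
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Generates mutation (M), transcript (E) and replicate-level protein (D)
#' layers, sample annotation, a drug response table and the planted truth
#' used by downstream tests. Per feature, the line-level transcript is
#' Gaussian on the log2 scale; the line-level protein shares a coupling
#' component with its cognate transcript (calibrated to the target
#' feature-wise correlation), a per-complex latent factor for complex
#' members, and an independent residual. Protein replicates add
#' biological noise (groups 1-3); the technical replicate (group 4)
#' re-measures group 3 with smaller noise plus an additive batch offset.
#' Missingness in D is intensity-dependent. The drug response is a sparse
#' linear function of standardized line-level protein features plus
#' Gaussian noise.
#'
#' @param spec a [cohort_sim_spec()].
#' @return a list of class `cohort_sim` with elements `matrices` (list
#'   `M`, `E`, `D` of [omics_matrix()]), `annotation`, `response`,
#'   `catalog` (the synthetic [complex_catalog()]) and `truth` (planted
#'   predictors per drug, realized missing fraction, coupling used).
#' @examples
#' sim <- simulate_cohort(cohort_sim_spec(n_cell_lines = 10, n_tnbc = 5,
#'                                        n_proteins = 50, seed = 1))
#' sim$matrices$D
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  nl <- spec$n_cell_lines
  np <- spec$n_proteins
  lines <- sprintf("line%02d", seq_len(nl))
  tnbc <- c(rep(TRUE, spec$n_tnbc), rep(FALSE, nl - spec$n_tnbc))
  subtype <- ifelse(tnbc,
                    rep(c("basal_a", "basal_b"), length.out = nl),
                    rep(c("luminal", "her2"), length.out = nl))
  prot <- sprintf("P%04d", seq_len(np))

  # disjoint synthetic complex catalog over the protein ids
  sizes <- sample(seq(spec$complex_size_range[1L], spec$complex_size_range[2L]),
                  spec$n_complexes, replace = TRUE)
  if (sum(sizes) > np) stop("complex catalog larger than the proteome")
  pool <- sample(prot, sum(sizes))
  cat_members <- split(pool, rep(seq_along(sizes), sizes))
  names(cat_members) <- sprintf("CPX%03d", seq_along(sizes))
  catalog <- complex_catalog(cat_members)
  cpx_of <- stats::setNames(rep(NA_integer_, np), prot)
  for (i in seq_along(cat_members)) cpx_of[cat_members[[i]]] <- i

  # line-level transcript and protein layers
  mu_t <- stats::rnorm(np, 8, 1.5)
  mu_p <- stats::rnorm(np, 18, 2)     # log-normal linear-scale baselines
  z <- matrix(stats::rnorm(np * nl), np, nl)            # shared biology
  a <- spec$protein_mrna_r
  w <- sqrt(spec$complex_cor)
  g <- matrix(stats::rnorm(spec$n_complexes * nl), spec$n_complexes, nl)
  in_cpx <- !is.na(cpx_of)
  e_sd <- sqrt(1 - a^2 - ifelse(in_cpx, w^2, 0))
  E_line <- mu_t + z                                     # sd 1 per feature
  P_line <- mu_p + a * z + e_sd * matrix(stats::rnorm(np * nl), np, nl)
  P_line[in_cpx, ] <- P_line[in_cpx, ] + w * g[cpx_of[in_cpx], , drop = FALSE]
  dimnames(E_line) <- list(prot, lines)
  dimnames(P_line) <- list(prot, lines)
  if (spec$n_transcripts > np) {
    extra <- matrix(stats::rnorm((spec$n_transcripts - np) * nl, 8, 1.5),
                    spec$n_transcripts - np, nl,
                    dimnames = list(sprintf("T%04d", seq_len(spec$n_transcripts - np) + np),
                                    lines))
    E_line <- rbind(E_line, extra)
  } else if (spec$n_transcripts < np) {
    E_line <- E_line[seq_len(spec$n_transcripts), , drop = FALSE]
  }

  # replicate-level protein matrix: groups 1-3 biological, group 4
  # technical re-measurement of group 3 with a batch offset
  reps <- lapply(1:3, function(gp)
    P_line + matrix(stats::rnorm(np * nl, 0, spec$bio_sd), np, nl))
  reps[[4L]] <- reps[[3L]] +
    matrix(stats::rnorm(np * nl, 0, spec$tech_sd), np, nl) + spec$batch_offset
  D <- do.call(cbind, lapply(1:4, function(gp) {
    m <- reps[[gp]]
    colnames(m) <- sprintf("%s_g%d", lines, gp)
    m
  }))
  D <- apply_mnar_missing(D, spec$target_missing_fraction, spec$missing_slope)
  realized_missing <- mean(is.na(D))

  # mutation layer
  mut_ids <- sprintf("MUT%03d", seq_len(spec$n_mutations))
  rates <- stats::runif(spec$n_mutations, 0.02, 0.3)
  M <- matrix(stats::rbinom(spec$n_mutations * nl, 1, rep(rates, nl)),
              spec$n_mutations, nl, dimnames = list(mut_ids, lines))

  # sparse linear drug response on standardized line-level protein values
  drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
  pred <- stats::setNames(vector("list", spec$n_drugs), drugs)
  Y <- matrix(NA_real_, nl, spec$n_drugs, dimnames = list(lines, drugs))
  Pz <- t(scale(t(P_line)))
  for (d in seq_len(spec$n_drugs)) {
    ids <- if (spec$n_predictors_per_drug > 0)
      sample(prot, spec$n_predictors_per_drug) else character()
    beta <- rep(spec$predictor_beta, length(ids))
    y <- -6 + if (length(ids))
      drop(crossprod(Pz[ids, , drop = FALSE], beta)) else 0
    y <- y + stats::rnorm(nl, 0, spec$response_noise_sd)
    if (spec$response_missing_fraction > 0)
      y[stats::runif(nl) < spec$response_missing_fraction] <- NA_real_
    Y[, d] <- y
    pred[[d]] <- list(ids = ids, beta = beta)
  }

  ann_rep <- data.frame(
    sample_id = colnames(D),
    cell_line = rep(lines, 4L),
    subtype = rep(subtype, 4L),
    tnbc = rep(tnbc, 4L),
    replicate_group = rep(1:4, each = nl),
    replicate_type = rep(c("biological", "biological", "biological",
                           "technical"), each = nl),
    batch = rep(c("MS1", "MS1", "MS1", "MS2"), each = nl))
  ann_line <- data.frame(
    sample_id = lines, cell_line = lines, subtype = subtype, tnbc = tnbc,
    replicate_group = 1L, replicate_type = "biological", batch = "external")
  ann <- sample_annotation(rbind(ann_rep, ann_line))

  structure(list(
    matrices = list(M = omics_matrix(M, "mutation"),
                    E = omics_matrix(E_line, "transcript"),
                    D = omics_matrix(D, "protein")),
    annotation = ann,
    response = drug_response_table(Y),
    catalog = catalog,
    truth = list(predictors = pred,
                 realized_missing_fraction = realized_missing,
                 coupling = a,
                 line_protein = P_line),
    spec = spec), class = "cohort_sim")
}

#' Specification of a synthetic perturbation time course
#'
#' Parameterizes [simulate_timecourse()]. Defaults emulate the study's
#' perturbation design: 9 cell lines (5 TNBC), 3 drugs, six time points
#' (0, 4, 12, 24, 48, 72 h) and 3 biological replicates, with planted
#' monotone responders, a planted subtype-opposite set (direction flipped
#' between TNBC and non-TNBC lines), transient responders that return to
#' baseline, and IC50-tracking proteins whose abundance follows the
#' line's log10 IC50 at every time point.
#'
#' @param n_lines,n_tnbc number of cell lines and how many are TNBC.
#' @param drugs character vector of drug names.
#' @param time_points_h time points in hours (must start at 0).
#' @param n_replicates biological replicates per condition.
#' @param n_proteins total proteins including planted sets.
#' @param n_monotone_per_drug planted consistently up-regulated proteins
#'   per drug (same direction in all lines).
#' @param monotone_fc linear-scale fold change between 72 h and baseline
#'   for planted monotone proteins.
#' @param n_opposite planted opposite-dynamics proteins (up in TNBC, down
#'   in non-TNBC; applied under every drug).
#' @param opposite_fc linear-scale last/first fold change of the opposite
#'   set (within the up-regulated group).
#' @param n_transient planted transient responders (shifted at 4-24 h,
#'   back to baseline by 48 h).
#' @param n_ic50_per_drug planted IC50-tracking proteins per drug.
#' @param ic50_r target per-time-point Pearson correlation between an
#'   IC50-tracking protein and log10 IC50 across lines.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param target_missing_fraction intensity-dependent missingness target.
#' @param missing_slope logistic scale of the missingness model.
#' @param seed integer random seed.
#' @return a list of class `timecourse_sim_spec`.
#' @export
timecourse_sim_spec <- function(n_lines = 9L, n_tnbc = 5L,
                                drugs = c("lapatinib", "everolimus", "MK2206"),
                                time_points_h = c(0, 4, 12, 24, 48, 72),
                                n_replicates = 3L,
                                n_proteins = 1000L,
                                n_monotone_per_drug = 30L,
                                monotone_fc = 4,
                                n_opposite = 25L,
                                opposite_fc = 4,
                                n_transient = 15L,
                                n_ic50_per_drug = 10L,
                                ic50_r = 0.8,
                                noise_sd = 0.2,
                                target_missing_fraction = 0.15,
                                missing_slope = 1.5,
                                seed = 1L) {
  spec <- as.list(environment())
  if (spec$monotone_fc <= 0 || spec$opposite_fc <= 0)
    stop("fold changes must be > 0")
  if (spec$n_tnbc >= spec$n_lines || spec$n_tnbc < 1)
    stop("need at least one TNBC and one non-TNBC line")
  n_planted <- length(drugs) * (spec$n_monotone_per_drug + spec$n_ic50_per_drug) +
    spec$n_opposite + spec$n_transient
  if (n_planted > spec$n_proteins)
    stop("planted sets exceed n_proteins; they must be disjoint from background")
  structure(spec, class = "timecourse_sim_spec")
}

#' Generate a synthetic perturbation time course with planted ground truth
#'
#' Planted monotone and opposite-dynamics proteins follow geometric
#' interpolation on the log2 scale from baseline at 0 h to baseline x FC
#' at 72 h (sign flipped in the non-TNBC group for the opposite set).
#' IC50-tracking proteins carry an offset proportional to the line's
#' standardized log10 IC50 at every time point, with per-(line, time)
#' noise calibrated to the target correlation. Replicate noise is added
#' on the log2 scale and missingness is intensity-dependent.
#'
#' @param spec a [timecourse_sim_spec()].
#' @return a list of class `timecourse_sim` with elements `experiment`
#'   (a [timecourse_experiment()]), `response` (log10 IC50
#'   [drug_response_table()]) and `truth` (planted protein sets and the
#'   realized missing fraction).
#' @export
simulate_timecourse <- function(spec = timecourse_sim_spec()) {
  stopifnot(inherits(spec, "timecourse_sim_spec"))
  set.seed(spec$seed)
  nl <- spec$n_lines; nt <- length(spec$time_points_h)
  nr <- spec$n_replicates; np <- spec$n_proteins
  lines <- sprintf("L%d", seq_len(nl))
  tnbc <- c(rep(TRUE, spec$n_tnbc), rep(FALSE, nl - spec$n_tnbc))
  prot <- sprintf("P%04d", seq_len(np))
  drugs <- spec$drugs

  # disjoint planted sets
  remaining <- prot
  take <- function(n) {
    if (n == 0L) return(character())
    ids <- remaining[seq_len(n)]
    remaining <<- remaining[-seq_len(n)]
    ids
  }
  monotone <- stats::setNames(
    lapply(drugs, function(d) take(spec$n_monotone_per_drug)), drugs)
  opposite <- take(spec$n_opposite)
  transient <- take(spec$n_transient)
  ic50_track <- stats::setNames(
    lapply(drugs, function(d) take(spec$n_ic50_per_drug)), drugs)

  baseline <- stats::setNames(stats::rnorm(np, 18, 2), prot)
  resp <- matrix(stats::rnorm(nl * length(drugs), -6, 0.8), nl,
                 dimnames = list(lines, drugs))
  resp_z <- scale(resp)   # standardized log10 IC50 per drug

  frac <- spec$time_points_h / max(spec$time_points_h)
  bump <- stats::approx(c(0, 4, 12, 24, 48, 72), c(0, 1, 1, 1, 0, 0),
                        xout = spec$time_points_h)$y
  # per-(line,time) noise sd giving the target correlation for tracking
  # proteins, after replicate averaging
  rep_var <- spec$noise_sd^2 / nr
  extra_var <- max(1 / spec$ic50_r^2 - 1 - rep_var, 0)

  samples <- expand.grid(replicate = seq_len(nr),
                         time_h = spec$time_points_h,
                         drug = drugs, cell_line = lines,
                         stringsAsFactors = FALSE)
  samples$tnbc <- tnbc[match(samples$cell_line, lines)]
  samples$sample_id <- sprintf("%s_%s_t%g_r%d", samples$cell_line,
                               samples$drug, samples$time_h, samples$replicate)
  samples <- samples[, c("sample_id", "cell_line", "tnbc", "drug",
                         "time_h", "replicate")]

  values <- matrix(rep(baseline, nrow(samples)), np, nrow(samples),
                   dimnames = list(prot, samples$sample_id))
  ti <- match(samples$time_h, spec$time_points_h)
  for (d in drugs) {
    sel_d <- samples$drug == d
    # monotone responders: log2-linear ramp to log2(FC) at 72 h
    values[monotone[[d]], sel_d] <-
      values[monotone[[d]], sel_d] +
      rep(log2(spec$monotone_fc) * frac[ti[sel_d]], each = length(monotone[[d]]))
    # opposite set: ramp up in TNBC, down in non-TNBC
    sgn <- ifelse(samples$tnbc[sel_d], 1, -1)
    values[opposite, sel_d] <- values[opposite, sel_d] +
      rep(sgn * log2(spec$opposite_fc) * frac[ti[sel_d]],
          each = length(opposite))
    # transient responders: shifted mid-course, back to baseline
    values[transient, sel_d] <- values[transient, sel_d] +
      rep(log2(3) * bump[ti[sel_d]], each = length(transient))
    # IC50-tracking proteins: line offset + per-(line,time) jitter
    z <- resp_z[match(samples$cell_line[sel_d], lines), d]
    ids <- ic50_track[[d]]
    jit <- matrix(stats::rnorm(length(ids) * nl * nt, 0, sqrt(extra_var)),
                  length(ids), nl * nt)
    key <- (match(samples$cell_line[sel_d], lines) - 1L) * nt + ti[sel_d]
    values[ids, sel_d] <- values[ids, sel_d] + rep(z, each = length(ids)) +
      jit[, key, drop = FALSE]
  }
  if (spec$noise_sd > 0)
    values <- values + matrix(stats::rnorm(length(values), 0, spec$noise_sd),
                              nrow(values))
  values <- apply_mnar_missing(values, spec$target_missing_fraction,
                               spec$missing_slope)

  tc <- timecourse_experiment(values, samples, spec$time_points_h)
  structure(list(
    experiment = tc,
    response = drug_response_table(resp),
    truth = list(monotone = monotone, opposite = opposite,
                 transient = transient, ic50_tracking = ic50_track,
                 ic50_sign = 1,
                 realized_missing_fraction = mean(is.na(values))),
    spec = spec), class = "timecourse_sim")
}

#' Write a simulated cohort or time course to a directory of TSV files
#'
#' Writes the standard matrix/annotation/response TSVs plus a
#' `truth_*.tsv` listing of the planted feature sets.
#'
#' @param sim a `cohort_sim` or `timecourse_sim`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sim, "cohort_sim")) {
    for (nm in names(sim$matrices))
      write_matrix(sim$matrices[[nm]], file.path(dir, paste0(nm, ".tsv")))
    write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
    write_drug_response(sim$response, file.path(dir, "response.tsv"))
    write_complexes(sim$catalog, file.path(dir, "complexes.tsv"))
    truth <- do.call(rbind, lapply(names(sim$truth$predictors), function(d)
      if (length(sim$truth$predictors[[d]]$ids))
        data.frame(drug = d, feature = sim$truth$predictors[[d]]$ids,
                   beta = sim$truth$predictors[[d]]$beta)))
    if (!is.null(truth))
      utils::write.table(truth, file.path(dir, "truth_predictors.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(sim, "timecourse_sim")) {
    utils::write.table(sim$experiment$samples, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix(omics_matrix(sim$experiment$values, "protein"),
                 file.path(dir, "timecourse.tsv"))
    write_drug_response(sim$response, file.path(dir, "response.tsv"))
    sets <- c(list(opposite = sim$truth$opposite,
                   transient = sim$truth$transient),
              stats::setNames(sim$truth$monotone,
                              paste0("monotone_", names(sim$truth$monotone))),
              stats::setNames(sim$truth$ic50_tracking,
                              paste0("ic50_", names(sim$truth$ic50_tracking))))
    truth <- data.frame(set = rep(names(sets), lengths(sets)),
                        feature = unlist(sets, use.names = FALSE))
    utils::write.table(truth, file.path(dir, "truth_sets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else stop("unknown simulation object")
  invisible(dir)
}
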