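#' Run the cohort analysis workflow
#'
#' Wires the stages of the cohort analysis in order: matrix QC
#' (filtering, outlier removal, batch centering, replicate averaging),
#' protein-complex co-expression at protein vs transcript level, TNBC
#' differential expression with signature selection, and elastic-net
#' drug-response prediction across omics-layer combinations. Inputs can
#' be supplied explicitly or simulated from a [cohort_sim_spec()].
#'
#' @param data list with elements `matrices` (named list of
#'   [omics_matrix()]: at least `D`; optionally `E`, `M`), `annotation`,
#'   `response`, `catalog` -- exactly the shape returned by
#'   [simulate_cohort()]. Ignored when `cohort_spec` is given.
#' @param cohort_spec optional [cohort_sim_spec()]; when given, the
#'   cohort is simulated first.
#' @param config a [run_config()].
#' @param en_config an [en_config()] for the prediction stage.
#' @param combos layer combinations for the prediction stage.
#' @param drugs drugs to model (default: all in the response table).
#' @param out_dir optional directory; when given, result tables are
#'   written as TSVs alongside a `manifest.tsv`.
#' @return list of class `cohort_result` with elements `qc`,
#'   `complexes`, `de`, `signature`, `separation`, `prediction`,
#'   `manifest`.
#' @export
run_cohort_pipeline <- function(data = NULL, cohort_spec = NULL,
                                config = run_config(),
                                en_config = en_config("fast"),
                                combos = "D", drugs = NULL,
                                out_dir = NULL) {
  if (!is.null(cohort_spec)) data <- simulate_cohort(cohort_spec)
  if (is.null(data$matrices$D) || is.null(data$annotation))
    stop("pipeline needs at least a protein matrix 'D' and an annotation")
  message(sprintf("[proteodyn] cohort pipeline: seed %d, stages qc>complexes>de>enpredict",
                  config$seed))
  qc <- qc_pipeline(data$matrices$D, data$annotation, config)
  avg <- qc$averaged

  cpx <- if (!is.null(data$catalog) && !is.null(data$matrices$E)) {
    complex_coexpression(avg, data$matrices$E, data$catalog, config)
  }

  ann_line <- data$annotation[match(sample_ids(avg),
                                    data$annotation$cell_line), ]
  de <- differential_expression(avg, ann_line$tnbc,
                                p_threshold = config$de_p_threshold,
                                fc_up = config$de_fc_up,
                                fc_down = config$de_fc_down,
                                equal_variance = config$de_equal_variance)
  sig <- if (sum(de$is_dep) >= 2L)
    suppressWarnings(select_signature(de, config$de_signature_n))
  sep <- if (!is.null(sig) && length(sig) >= 2L) {
    ann_avg <- data$annotation
    ann_avg <- ann_avg[match(sample_ids(avg), ann_avg$cell_line), ]
    ann_avg$sample_id <- ann_avg$cell_line
    tryCatch(signature_separation(avg, sample_annotation(ann_avg), sig),
             error = function(e) NA_real_)
  }

  pred <- if (!is.null(data$response)) {
    layers <- c(list(D = avg), data$matrices[setdiff(names(data$matrices), "D")])
    if (is.null(drugs)) drugs <- colnames(data$response)
    compare_layer_combos(layers, data$response, combos, drugs,
                         en_config, seed = config$seed)
  }

  manifest <- list(stages = c("qc", "complexes", "de", "enpredict"),
                   seed = config$seed,
                   config = unclass(config),
                   en_config = unclass(en_config),
                   version = as.character(utils::packageVersion("proteodyn")))
  res <- structure(list(qc = qc, complexes = cpx, de = de, signature = sig,
                        separation = sep, prediction = pred,
                        manifest = manifest), class = "cohort_result")
  if (!is.null(out_dir)) write_cohort_result(res, out_dir)
  res
}

write_cohort_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$qc$replicate_correlations$pairs, "replicate_correlations.tsv")
  w(res$qc$cv_by_abundance, "cv_by_abundance.tsv")
  if (!is.null(res$complexes)) w(res$complexes$pairs, "complex_pairs.tsv")
  w(res$de, "dep_table.tsv")
  if (!is.null(res$signature))
    writeLines(res$signature, file.path(out_dir, "signature.txt"))
  if (!is.null(res$prediction)) w(res$prediction, "predictive_power.tsv")
  cfg <- res$manifest$config
  w(data.frame(key = names(cfg), value = vapply(cfg, paste, character(1),
                                                collapse = ",")),
    "manifest.tsv")
  invisible(out_dir)
}

#' Run the drug-perturbation analysis workflow
#'
#' Summarizes the time course to mean profiles, screens proteins whose
#' expression tracks IC50 across lines, clusters z-scored mean profiles
#' per subtype group with fuzzy c-means, selects opposite-dynamics
#' proteins, applies the pathway-consistency filter and detects
#' persistently dysregulated proteins per drug.
#'
#' @param data list with `experiment` (a [timecourse_experiment()]) and
#'   `response` (a [drug_response_table()]) -- the shape returned by
#'   [simulate_timecourse()]. Ignored when `timecourse_spec` is given.
#' @param timecourse_spec optional [timecourse_sim_spec()].
#' @param pathways optional [pathway_annotation()] for the consistency
#'   filter.
#' @param config a [run_config()].
#' @param out_dir optional output directory for TSV results.
#' @return list of class `perturbation_result` with elements
#'   `profiles`, `ic50_screen`, `clustering` (per drug x subtype group),
#'   `selection`, `pathway_table`, `pdp` (per drug), `manifest`.
#' @export
run_perturbation_pipeline <- function(data = NULL, timecourse_spec = NULL,
                                      pathways = NULL,
                                      config = run_config(),
                                      out_dir = NULL) {
  if (!is.null(timecourse_spec)) data <- simulate_timecourse(timecourse_spec)
  message(sprintf("[proteodyn] perturbation pipeline: seed %d", config$seed))
  tc <- data$experiment
  prof <- summarize_timecourse(tc)
  screen <- ic50_screen(prof, data$response, config$dyn_tau,
                        config$dyn_max_missing_timepoints)
  drugs <- prof$drugs
  if (!length(drugs)) warning("no drugs in the time course; nothing to do")

  clustering <- list()
  for (d in drugs) for (grp in c("tnbc", "non_tnbc")) {
    in_grp <- if (grp == "tnbc") prof$tnbc else !prof$tnbc
    gm <- apply(prof$profiles[, in_grp, d, , drop = FALSE], c(1L, 4L),
                mean, na.rm = TRUE)
    gm[is.nan(gm)] <- NA_real_
    z <- zscore_profiles(gm)
    if (nrow(z$z) >= config$dyn_clusters)
      clustering[[paste(d, grp, sep = ".")]] <-
        fuzzy_cmeans(z$z, config$dyn_clusters, config$dyn_fuzzifier,
                     seed = config$seed)
  }

  selection <- opposite_dynamics_select(tc, config)
  pw_tab <- if (!is.null(pathways))
    pathway_consistency(selection, pathways, config$dyn_tnbc_min,
                        config$dyn_non_tnbc_min)
  pdp <- stats::setNames(lapply(drugs, function(d)
    pdp_detect(tc, d, config$pdp_frac_threshold, config$de_p_threshold,
               config$de_fc_up, config$de_fc_down)), drugs)

  manifest <- list(stages = c("summarize", "ic50_screen", "mfuzz",
                              "opposite_dynamics", "pathways", "pdp"),
                   seed = config$seed, config = unclass(config),
                   version = as.character(utils::packageVersion("proteodyn")))
  res <- structure(list(profiles = prof, ic50_screen = screen,
                        clustering = clustering, selection = selection,
                        pathway_table = pw_tab, pdp = pdp,
                        manifest = manifest),
                   class = "perturbation_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(screen, file.path(out_dir, "ic50_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selection$selected,
                       file.path(out_dir, "opposite_dynamics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pw_tab))
      utils::write.table(pw_tab, file.path(out_dir, "pathway_consistency.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (d in names(pdp))
      writeLines(pdp[[d]], file.path(out_dir, paste0("pdp_", d, ".txt")))
  }
  res
}
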