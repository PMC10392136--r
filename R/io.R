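#' Read an omics matrix from TSV
#'
#' Expected dialect: tab-separated, header row of sample ids, first column
#' feature ids, literal `NA` for missing cells.
#'
#' @param path file path.
#' @param layer_name layer label for the returned matrix.
#' @return an [omics_matrix()].
#' @export
read_matrix <- function(path, layer_name = "protein") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (nrow(raw) == 0L) stop("no features in ", path)
  fid <- raw[[1L]]
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1L])
  body <- raw[, -1L, drop = FALSE]
  v <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(fid, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & !(cell %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s' of %s",
                   cell[bad[1L]], bad[1L], colnames(body)[j], path))
    v[, j] <- num
  }
  omics_matrix(v, layer_name)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix()]: round-tripping reproduces the values up to
#' float formatting.
#'
#' @param m an [omics_matrix()].
#' @param path output file path.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, digits = 10) {
  v <- m$values
  out <- data.frame(feature_id = rownames(v),
                    signif(v, digits),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample annotation TSV
#'
#' Columns: `sample_id`, `cell_line`, `subtype`, `tnbc` (TRUE/FALSE),
#' `replicate_group`, `replicate_type`, `batch`.
#'
#' @param path file path.
#' @return a [sample_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$tnbc <- as.logical(df$tnbc)
  sample_annotation(df)
}

#' @rdname read_annotation
#' @param ann a [sample_annotation()].
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path file path.
#' @return a [pathway_annotation()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(pathway_annotation(stats::setNames(list(), character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  members <- lapply(parts, function(p) {
    if (length(p) < 3L) stop("GMT line with no members: ", p[[1L]])
    p[-(1:2)]
  })
  pathway_annotation(stats::setNames(members, ids))
}

#' @rdname read_gmt
#' @param pw a [pathway_annotation()].
#' @export
write_gmt <- function(pw, path) {
  lines <- vapply(names(pw), function(id) {
    paste(c(id, "na", pw[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-complex catalog TSV
#'
#' Two columns: `complex_id`, `member` (one row per membership).
#'
#' @param path file path.
#' @return a [complex_catalog()].
#' @export
read_complexes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("complex_id", "member") %in% names(df)))
    stop("complex catalog needs columns 'complex_id' and 'member'")
  complex_catalog(split(as.character(df$member), df$complex_id))
}

#' @rdname read_complexes
#' @param cat a [complex_catalog()].
#' @export
write_complexes <- function(cat, path) {
  df <- data.frame(
    complex_id = rep(names(cat), lengths(cat)),
    member = unlist(cat, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug response TSV
#'
#' First column `cell_line`, remaining columns one per drug, values log10
#' IC50 (molar), `NA` allowed.
#'
#' @param path file path.
#' @return a [drug_response_table()].
#' @export
read_drug_response <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- as.character(df[[1L]])
  drug_response_table(v)
}

#' @rdname read_drug_response
#' @param resp a [drug_response_table()].
#' @export
write_drug_response <- function(resp, path) {
  out <- data.frame(cell_line = rownames(resp),
                    unclass(resp), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Default run configuration
#'
#' Collects every threshold and grid the pipeline uses, so a run is fully
#' reproducible from (inputs, config, seed). Values default to the study
#' conditions; any entry can be overridden by name.
#'
#' @param ... named overrides of the defaults.
#' @return a named list with class `run_config`.
#' @examples
#' cfg <- run_config(seed = 7, de_p_threshold = 0.01)
#' cfg$de_p_threshold
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    qc_max_missing_fraction = 0.9,
    qc_outlier_z = 3,
    qc_cv_bins = 3,
    complex_min_obs = 3,
    de_p_threshold = 0.05,
    de_fc_up = 1.5,
    de_fc_down = 0.67,
    de_signature_n = 38,
    de_equal_variance = TRUE,
    impute_k = 10,
    en_preset = "fast",
    dyn_tau = 0.7,
    dyn_max_missing_timepoints = 1,
    dyn_fuzzifier = 2.0,
    dyn_clusters = 6,
    dyn_anova_p = 0.05,
    dyn_min_fc = 2,
    dyn_monotone_rho = 0.8,
    dyn_intersect_drugs = FALSE,
    dyn_tnbc_min = 3 / 5,
    dyn_non_tnbc_min = 2 / 4,
    pdp_frac_threshold = 0.6)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of key-value overrides of [run_config()] defaults.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  do.call(run_config, yaml::yaml.load_file(path))
}
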