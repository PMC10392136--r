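#' Construct an omics matrix
#'
#' An `omics_matrix` is one omics layer: a features x samples matrix of
#' log2 abundances (protein, transcript or RPPA layers) or of 0/1 calls
#' (mutation layer), with `NA` as the explicit missing marker. DIA
#' proteomic matrices routinely carry ~35% missingness, so missing values
#' are first-class throughout: they are never encoded as sentinel numbers
#' and all downstream statistics use pairwise-complete observations.
#'
#' @param values numeric matrix with feature ids as rownames and sample
#'   ids as colnames.
#' @param layer_name single string naming the layer (e.g. `"protein"`,
#'   `"transcript"`, `"mutation"`, `"rppa"`).
#' @return An object of class `omics_matrix`: a list with elements
#'   `layer_name` and `values`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
#' om <- omics_matrix(m, "protein")
#' dim(om)
#' @export
omics_matrix <- function(values, layer_name = "protein") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature ids as rownames and sample ids as colnames")
  if (nrow(values) == 0L) stop("no features")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (!is.character(layer_name) || length(layer_name) != 1L)
    stop("'layer_name' must be a single string")
  obs <- values[!is.na(values)]
  if (identical(layer_name, "mutation")) {
    if (anyNA(values)) stop("mutation layer must not contain missing values")
    if (!all(obs %in% c(0, 1))) stop("mutation layer must contain only 0/1")
  } else if (any(!is.finite(obs))) {
    stop("non-finite value in intensity layer '", layer_name, "'")
  }
  structure(list(layer_name = layer_name, values = values),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
dimnames.omics_matrix <- function(x) dimnames(x$values)

#' Feature and sample ids of an omics matrix
#' @param m an [omics_matrix()].
#' @return character vector of ids.
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Fraction of missing cells in an omics matrix
#' @param m an [omics_matrix()].
#' @return a number in \[0, 1\].
#' @export
missing_fraction <- function(m) mean(is.na(m$values))

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix '%s': %d features x %d samples (%.1f%% missing)\n",
              x$layer_name, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

# subset, keeping class and validity
subset_omics <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  omics_matrix(v, m$layer_name)
}

#' Construct a sample annotation table
#'
#' Per-sample metadata tying opaque sample ids to cell line, molecular
#' subtype, TNBC status, replicate structure and measurement batch. Every
#' sample id appearing in an omics matrix must have exactly one row here;
#' the replicate design is three biological replicates (groups 1-3) plus
#' one technical replicate of the third (group 4).
#'
#' @param df data.frame with columns `sample_id`, `cell_line`, `subtype`
#'   (one of `"basal_a"`, `"basal_b"`, `"luminal"`, `"her2"`), `tnbc`
#'   (logical), `replicate_group` (integer 1-4), `replicate_type`
#'   (`"biological"` or `"technical"`), `batch` (character).
#' @return the validated data.frame with class `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  req <- c("sample_id", "cell_line", "subtype", "tnbc",
           "replicate_group", "replicate_type", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$cell_line <- as.character(df$cell_line)
  df$subtype <- as.character(df$subtype)
  df$batch <- as.character(df$batch)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in annotation: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$subtype), c("basal_a", "basal_b", "luminal", "her2"))
  if (length(bad)) stop("unknown subtype token: ", bad[1L])
  if (!is.logical(df$tnbc) || anyNA(df$tnbc))
    stop("'tnbc' must be logical without missing values")
  if (!all(df$replicate_group %in% 1:4))
    stop("replicate_group must be in 1..4")
  df$replicate_group <- as.integer(df$replicate_group)
  if (!all(df$replicate_type %in% c("biological", "technical")))
    stop("replicate_type must be 'biological' or 'technical'")
  # tnbc must be a deterministic function of cell_line
  agg <- tapply(df$tnbc, df$cell_line, function(z) length(unique(z)))
  if (any(agg > 1L))
    stop("inconsistent tnbc flag within cell line: ",
         names(agg)[agg > 1L][1L])
  class(df) <- c("sample_annotation", "data.frame")
  df
}

# check every matrix sample is annotated; return annotation rows aligned
# to the matrix columns
join_annotation <- function(m, ann) {
  idx <- match(sample_ids(m), ann$sample_id)
  if (anyNA(idx))
    stop("sample(s) in matrix but absent from annotation: ",
         paste(utils::head(sample_ids(m)[is.na(idx)], 5L), collapse = ", "))
  ann[idx, , drop = FALSE]
}

#' Construct a drug response table
#'
#' @param values numeric matrix, cell lines x drugs, of log10 IC50 values
#'   (molar); `NA` where a line was not screened for a drug.
#' @return matrix with class `drug_response_table`.
#' @export
drug_response_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("drug response table needs cell-line rownames and drug colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate cell line or drug id")
  if (any(!is.finite(values[!is.na(values)])))
    stop("non-finite drug response value")
  structure(values, class = c("drug_response_table", class(values)))
}

#' Construct a protein-complex catalog
#'
#' @param members named list; each element a character vector of member
#'   feature ids of one complex (size >= 1).
#' @return named list with class `complex_catalog`.
#' @export
complex_catalog <- function(members) {
  if (is.null(names(members)) || any(names(members) == ""))
    stop("every complex needs an id")
  members <- lapply(members, function(x) {
    x <- as.character(x)
    if (length(x) < 1L) stop("complex with no members")
    if (anyDuplicated(x)) stop("duplicate member within a complex")
    x
  })
  structure(members, class = "complex_catalog")
}

#' Construct a pathway annotation (GMT semantics)
#'
#' @param members named list; each element a non-empty character vector of
#'   member feature ids.
#' @return named list with class `pathway_annotation`.
#' @export
pathway_annotation <- function(members) {
  if (is.null(names(members)) || any(names(members) == ""))
    stop("every pathway needs an id")
  members <- lapply(members, function(x) {
    x <- unique(as.character(x))
    if (length(x) < 1L) stop("pathway with empty member set")
    x
  })
  structure(members, class = "pathway_annotation")
}

#' Construct a perturbation time-course experiment
#'
#' Holds a drug-perturbation proteome indexed by (cell line, drug, time,
#' replicate). The design has an untreated baseline at 0 h and five
#' post-treatment time points (4, 12, 24, 48, 72 h by default).
#'
#' @param values numeric matrix, proteins x samples (log2 intensities,
#'   `NA` allowed).
#' @param samples data.frame with one row per column of `values`:
#'   `sample_id`, `cell_line`, `tnbc` (logical), `drug`, `time_h`,
#'   `replicate`.
#' @param time_points_h strictly increasing numeric vector of time points;
#'   must include 0.
#' @return list with class `timecourse_experiment`.
#' @export
timecourse_experiment <- function(values, samples,
                                  time_points_h = c(0, 4, 12, 24, 48, 72)) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  req <- c("sample_id", "cell_line", "tnbc", "drug", "time_h", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("samples table must have one row per matrix column")
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("time points must be strictly increasing")
  if (time_points_h[1L] != 0) stop("baseline time 0 must be present")
  if (!all(samples$time_h %in% time_points_h))
    stop("sample at a time point not in 'time_points_h'")
  cond <- unique(samples[, c("cell_line", "drug", "time_h")])
  # every (line, drug) condition must cover every time point
  cnt <- table(cond$cell_line, cond$drug)
  if (any(cnt > 0 & cnt < length(time_points_h)))
    stop("every (cell line, drug) must have >=1 replicate at every time point")
  structure(list(values = values, samples = samples,
                 time_points_h = time_points_h),
            class = "timecourse_experiment")
}

#' @export
print.timecourse_experiment <- function(x, ...) {
  cat(sprintf(
    "timecourse_experiment: %d proteins, %d samples (%d lines x %d drugs x %d time points)\n",
    nrow(x$values), ncol(x$values), length(unique(x$samples$cell_line)),
    length(unique(x$samples$drug)), length(x$time_points_h)))
  invisible(x)
}
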