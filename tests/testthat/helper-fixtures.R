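# small in-code fixtures shared across test files

toy_matrix <- function(values, layer = "protein",
                       features = sprintf("P%d", seq_len(nrow(values))),
                       samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  omics_matrix(values, layer)
}

# annotation for one-row-per-sample toys: same cell line per replicate
# group block
toy_annotation <- function(sample_ids, cell_lines, groups = NULL,
                           tnbc = NULL, batch = NULL) {
  n <- length(sample_ids)
  if (is.null(groups)) groups <- rep(1L, n)
  if (is.null(tnbc)) tnbc <- rep(TRUE, n)
  if (is.null(batch)) batch <- rep("b1", n)
  sample_annotation(data.frame(
    sample_id = sample_ids, cell_line = cell_lines,
    subtype = ifelse(tnbc, "basal_a", "luminal"), tnbc = tnbc,
    replicate_group = groups,
    replicate_type = ifelse(groups == 4L, "technical", "biological"),
    batch = batch))
}

# independent brute-force Benjamini-Hochberg step-up, straight from the
# definition: adj_(i) = min_{j >= i} p_(j) * n / j, capped at 1
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# small deterministic cohort for QC-level tests
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_sim_spec(n_cell_lines = 12L, n_tnbc = 6L,
                                  n_proteins = 300L, n_complexes = 15L,
                                  n_mutations = 20L, n_drugs = 2L,
                                  seed = seed, ...))
}

# small deterministic time course
small_timecourse <- function(seed = 1, ...) {
  simulate_timecourse(timecourse_sim_spec(n_proteins = 300L,
                                          n_monotone_per_drug = 10L,
                                          n_opposite = 10L,
                                          n_transient = 5L,
                                          n_ic50_per_drug = 5L,
                                          seed = seed, ...))
}
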