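test_that("missing-rate filter removes strictly above the threshold", {
  v <- matrix(rnorm(30), 3, 10)
  v[1, 1:9] <- NA       # 0.9 exactly -> retained
  v[2, 1:10] <- NA      # 1.0 -> removed
  m <- toy_matrix(v)
  f <- filter_features_by_missing(m, 0.9)
  expect_identical(feature_ids(f), c("P1", "P3"))
  # all-missing features go for any threshold < 1
  expect_false("P2" %in% feature_ids(filter_features_by_missing(m, 0.99)))
  # idempotent
  expect_identical(filter_features_by_missing(f, 0.9)$values, f$values)
})

test_that("outlier detection is a robust z on identification counts", {
  v <- matrix(rnorm(200), 10, 20)
  m <- toy_matrix(v)
  expect_identical(detect_outlier_samples(m), character(0))  # equal counts

  v2 <- v
  v2[2:10, 20] <- NA    # sample 20 has 10% of the typical count
  m2 <- toy_matrix(v2)
  expect_identical(detect_outlier_samples(m2), "s20")
  expect_identical(detect_outlier_samples(m2, z_threshold = Inf),
                   character(0))
  # hand-computed robust z on varying counts
  counts <- c(100, 98, 102, 96, 104, 40)
  v3 <- matrix(NA_real_, 110, 6)
  for (j in seq_len(6)) v3[seq_len(counts[j]), j] <- 1
  z <- (counts - median(counts)) / mad(counts)
  expect_identical(detect_outlier_samples(toy_matrix(v3), 3),
                   paste0("s", which(z < -3)))
})

test_that("replicate correlations label pairs and order by design", {
  # duplicate column across groups 3/4 -> technical pair with r = 1
  v <- matrix(rnorm(40), 10, 4)
  v[, 4] <- v[, 3]
  m <- toy_matrix(v)
  ann <- toy_annotation(paste0("s", 1:4), rep("L1", 4), groups = 1:4)
  rc <- replicate_correlations(m, ann)
  tech <- rc$pairs[rc$pairs$label == "technical", ]
  expect_equal(nrow(tech), 1L)
  expect_equal(tech$r, 1)

  # exact collinearity at both signs
  v2 <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  m2 <- toy_matrix(v2)
  ann2 <- toy_annotation(paste0("s", 1:3), rep("L1", 3), groups = 1:3)
  rc2 <- replicate_correlations(m2, ann2)
  expect_equal(sort(rc2$pairs$r), c(-1, -1, 1))

  # pairs with < 3 co-observed features are skipped and counted
  v3 <- matrix(rnorm(20), 5, 4)
  v3[3:5, 1] <- NA; v3[1:3, 2] <- NA
  rc3 <- replicate_correlations(toy_matrix(v3),
                                toy_annotation(paste0("s", 1:4),
                                               rep("L1", 4), groups = 1:4))
  expect_gte(rc3$n_skipped, 1L)
})

test_that("simulated replicate structure orders technical > biological > non-replicate", {
  sim <- small_cohort(seed = 1, tech_sd = 0.05, bio_sd = 0.2)
  rc <- replicate_correlations(sim$matrices$D, sim$annotation)
  expect_gt(rc$medians[["technical"]], rc$medians[["biological"]])
  expect_gt(rc$medians[["biological"]], rc$medians[["non_replicate"]])
})

test_that("CV by abundance matches a direct linear-scale computation", {
  # two replicates per line, zero noise -> all CVs zero
  v <- matrix(rep(rnorm(10, 18, 2), 2), 10, 2)
  m <- toy_matrix(v)
  ann <- toy_annotation(c("s1", "s2"), c("L1", "L1"), groups = 1:2)
  cv <- cv_by_abundance(m, ann, n_bins = 1)
  expect_equal(cv$median_cv, 0)

  # log2 values {10, 10 + delta}: brute-force sd/mean oracle
  delta <- 0.1
  v2 <- matrix(c(10, 10 + delta), 1, 2,
               dimnames = list("P1", c("s1", "s2")))
  cv2 <- cv_by_abundance(omics_matrix(v2), ann, n_bins = 1)
  lin <- 2^c(10, 10 + delta)
  expect_equal(cv2$median_cv, sd(lin) / mean(lin))

  # quantile binning partitions all usable features
  sim <- small_cohort(seed = 2)
  cv3 <- cv_by_abundance(sim$matrices$D, sim$annotation, n_bins = 3)
  expect_equal(nrow(cv3), 3L)
  expect_true(all(cv3$median_cv >= 0))
})

test_that("batch centering equalizes batch means and keeps structure", {
  # single batch -> identity
  v <- matrix(rnorm(40), 10, 4)
  m <- toy_matrix(v)
  ann1 <- toy_annotation(paste0("s", 1:4), rep("L1", 4), groups = 1:4)
  expect_equal(batch_center(m, ann1)$values, m$values)

  # feature with batch means 5 and 7 (equal sizes) -> both 6
  v2 <- matrix(c(5, 5, 7, 7), 1, 4, dimnames = list("P1", paste0("s", 1:4)))
  ann2 <- toy_annotation(paste0("s", 1:4), rep("L1", 4), groups = 1:4,
                         batch = c("A", "A", "B", "B"))
  out <- batch_center(omics_matrix(v2), ann2)
  expect_equal(unname(out$values[1, ]), rep(6, 4))

  # grand mean preserved to 1e-9, within-batch variance unchanged,
  # missing pattern untouched
  set.seed(3)
  v3 <- matrix(rnorm(200), 20, 10)
  v3[sample(200, 30)] <- NA
  batches <- rep(c("A", "B"), each = 5)
  ann3 <- toy_annotation(paste0("s", 1:10), rep("L1", 10),
                         groups = rep(1:2, 5), batch = batches)
  m3 <- toy_matrix(v3)
  out3 <- batch_center(m3, ann3)
  expect_identical(is.na(out3$values), is.na(m3$values))
  expect_equal(rowMeans(out3$values, na.rm = TRUE),
               rowMeans(m3$values, na.rm = TRUE), tolerance = 1e-9)
  for (b in c("A", "B")) {
    cols <- which(batches == b)
    expect_equal(apply(out3$values[, cols], 1, var, na.rm = TRUE),
                 apply(m3$values[, cols], 1, var, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("a planted group-4 batch offset is removed by centering", {
  sim <- small_cohort(seed = 4, batch_offset = 1.0)
  ann <- sim$annotation
  centered <- batch_center(sim$matrices$D, ann)
  a <- proteodyn:::join_annotation(centered, ann)
  g4 <- a$batch == "MS2"
  offset <- mean(rowMeans(centered$values[, g4], na.rm = TRUE) -
                   rowMeans(centered$values[, !g4], na.rm = TRUE),
                 na.rm = TRUE)
  expect_lt(abs(offset), 0.05)
})

test_that("replicate averaging pools observed values per cell line", {
  v <- matrix(c(4, 6, NA, NA), 1, 4, dimnames = list("P1", paste0("s", 1:4)))
  ann <- toy_annotation(paste0("s", 1:4), rep("L1", 4), groups = 1:4)
  avg <- average_replicates(omics_matrix(v), ann)
  expect_equal(unname(avg$values[1, 1]), 5)

  v2 <- matrix(rep(rnorm(5), 4), 5, 4)
  avg2 <- average_replicates(toy_matrix(v2), ann)
  expect_equal(unname(avg2$values[, 1]), v2[, 1])

  # averaging k replicates shrinks noise roughly by 1/sqrt(k)
  set.seed(9)
  truth <- rnorm(400, 18, 2)
  reps <- sapply(1:4, function(i) truth + rnorm(400, 0, 0.4))
  m3 <- toy_matrix(reps)
  avg3 <- average_replicates(m3, ann)
  sd_rep <- sd(reps[, 1] - truth)
  sd_avg <- sd(avg3$values[, 1] - truth)
  expect_lt(sd_avg, sd_rep / sqrt(4) * 1.35)
  expect_gt(sd_avg, sd_rep / sqrt(4) / 1.35)
})

test_that("the full QC stage runs and reports", {
  sim <- small_cohort(seed = 6)
  qc <- qc_pipeline(sim$matrices$D, sim$annotation)
  expect_s3_class(qc, "qc_report")
  expect_lte(qc$missing_after, qc$missing_before)
  expect_lte(qc$n_features_after, qc$n_features_before)
  expect_equal(ncol(qc$averaged$values), 12L)
  expect_output(print(qc), "QC:")
})
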