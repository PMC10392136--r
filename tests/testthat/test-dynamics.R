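# minimal hand-built time course: nl lines x 1 drug x 6 times x nr reps
toy_timecourse <- function(values_fun, nl = 2, nr = 3, tnbc = c(TRUE, FALSE),
                           drug = "dr") {
  tp <- c(0, 4, 12, 24, 48, 72)
  samples <- expand.grid(replicate = seq_len(nr), time_h = tp,
                         cell_line = paste0("L", seq_len(nl)),
                         stringsAsFactors = FALSE)
  samples$drug <- drug
  samples$tnbc <- tnbc[match(samples$cell_line, paste0("L", seq_len(nl)))]
  samples$sample_id <- sprintf("%s_t%g_r%d", samples$cell_line,
                               samples$time_h, samples$replicate)
  samples <- samples[, c("sample_id", "cell_line", "tnbc", "drug",
                         "time_h", "replicate")]
  v <- values_fun(samples)
  timecourse_experiment(v, samples, tp)
}

test_that("time-course summarization averages observed replicates", {
  v_fun <- function(s) {
    v <- matrix(10, 2, nrow(s),
                dimnames = list(c("P1", "P2"), s$sample_id))
    # P1, L1, t=4: replicates (NA, 5, 7) -> mean 6
    cols <- which(s$cell_line == "L1" & s$time_h == 4)
    v["P1", cols] <- c(NA, 5, 7)
    v
  }
  tc <- toy_timecourse(v_fun)
  prof <- summarize_timecourse(tc)
  expect_equal(unname(prof$profiles["P1", "L1", "dr", "4"]), 6)
  expect_equal(unname(prof$n_replicates["P1", "L1", "dr", "4"]), 2L)
  # identical replicates -> profile equals the replicate
  expect_equal(unname(prof$profiles["P2", "L2", "dr", ]), rep(10, 6))
})

test_that("IC50 screening classifies constructed correlations exactly", {
  sim <- simulate_timecourse(timecourse_sim_spec(
    n_proteins = 100L, n_monotone_per_drug = 3L, n_opposite = 3L,
    n_transient = 2L, n_ic50_per_drug = 4L, ic50_r = 1, noise_sd = 0,
    target_missing_fraction = 0, seed = 61))
  prof <- summarize_timecourse(sim$experiment)
  scr <- ic50_screen(prof, sim$response)
  tracked <- scr[scr$drug == "lapatinib" &
                   scr$protein %in% sim$truth$ic50_tracking$lapatinib, ]
  expect_true(all(tracked$class == "resistance_associated"))
  expect_true(all(abs(tracked$mean_r - 1) < 1e-9))

  # constant protein everywhere -> no computable r -> excluded
  v <- sim$experiment$values
  v["P0100", ] <- 12
  tc2 <- timecourse_experiment(v, sim$experiment$samples)
  scr2 <- ic50_screen(summarize_timecourse(tc2), sim$response)
  expect_true(all(!scr2$eligible[scr2$protein == "P0100"]))
  expect_true(all(scr2$class[scr2$protein == "P0100"] == "none"))
})

test_that("IC50 screening is invariant to linear rescaling of the response", {
  sim <- small_timecourse(seed = 62)
  prof <- summarize_timecourse(sim$experiment)
  s1 <- ic50_screen(prof, sim$response)
  resp2 <- drug_response_table(sim$response[, ] * 3 + 10)
  s2 <- ic50_screen(prof, resp2)
  expect_equal(s1$mean_r, s2$mean_r, tolerance = 1e-12)
  expect_identical(s1$class, s2$class)
})

test_that("noisy planted IC50 trackers are usually classified at tau 0.7", {
  hits <- unlist(lapply(1:8, function(seed) {
    sim <- simulate_timecourse(timecourse_sim_spec(
      n_proteins = 150L, n_monotone_per_drug = 5L, n_opposite = 5L,
      n_transient = 3L, n_ic50_per_drug = 6L, ic50_r = 0.8,
      noise_sd = 0.2, seed = seed))
    prof <- summarize_timecourse(sim$experiment)
    scr <- ic50_screen(prof, sim$response, tau = 0.7)
    vapply(names(sim$truth$ic50_tracking), function(d) {
      ids <- sim$truth$ic50_tracking[[d]]
      mean(scr$class[scr$drug == d & scr$protein %in% ids] ==
             "resistance_associated")
    }, numeric(1))
  }))
  expect_gte(mean(hits), 0.8)
})

test_that("fuzzy c-means obeys its algebraic contract", {
  set.seed(63)
  # two well-separated shapes: ramps up and ramps down
  up <- t(replicate(30, seq(-1, 1, length.out = 6) + rnorm(6, 0, 0.1)))
  dn <- t(replicate(30, seq(1, -1, length.out = 6) + rnorm(6, 0, 0.1)))
  x <- proteodyn::zscore_profiles(rbind(up, dn))$z

  cl <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1)
  expect_equal(rowSums(cl$membership), rep(1, nrow(x)), tolerance = 1e-9)
  expect_true(all(diff(cl$objective) <= 1e-8))
  hard <- apply(cl$membership, 1, which.max)
  expect_equal(length(unique(hard[1:30])), 1L)
  expect_equal(length(unique(hard[31:60])), 1L)
  expect_false(hard[1] == hard[31])
  expect_true(all(apply(cl$membership, 1, max) > 0.9))

  # m -> 1 approaches hard assignment
  cl_hard <- fuzzy_cmeans(x, c = 2, m = 1.05, seed = 1)
  expect_gt(min(apply(cl_hard$membership, 1, max)), 0.999)

  # c = 1: all memberships one, centroid is the mean profile
  cl1 <- fuzzy_cmeans(x, c = 1)
  expect_equal(unname(cl1$membership[, 1]), rep(1, nrow(x)))
  expect_equal(drop(cl1$centroids), colMeans(x))

  # objective trace non-increasing on unstructured data too
  noise <- matrix(rnorm(50 * 6), 50)
  cl_n <- fuzzy_cmeans(proteodyn::zscore_profiles(noise)$z, c = 4,
                       m = 2, seed = 2)
  expect_true(all(diff(cl_n$objective) <= 1e-8))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(64)
  up <- t(replicate(25, seq(-1, 1, length.out = 6) + rnorm(6, 0, 0.15)))
  dn <- t(replicate(25, seq(1, -1, length.out = 6) + rnorm(6, 0, 0.15)))
  x <- proteodyn::zscore_profiles(rbind(up, dn))$z
  ours <- fuzzy_cmeans(x, c = 2, m = 2, seed = 3)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 500)
  # same partition up to label switching
  ours_hard <- apply(ours$membership, 1, which.max)
  ref_hard <- apply(ref$membership, 1, which.max)
  agree <- max(mean(ours_hard == ref_hard), mean(ours_hard != ref_hard))
  expect_equal(agree, 1)
  # centroids match up to permutation
  d <- as.matrix(dist(rbind(ours$centroids, ref$centers)))[1:2, 3:4]
  expect_lt(min(d[1, ]) + min(d[2, ]), 0.1)
})

test_that("trend statistics follow the constructed profiles", {
  # flat noiseless profile: p = 1, direction none
  flat_fun <- function(s) matrix(10, 1, nrow(s),
                                 dimnames = list("P1", s$sample_id))
  tc <- toy_timecourse(flat_fun)
  ts <- trend_stats(tc, "L1", "dr")
  expect_equal(ts$anova_p, 1)
  expect_identical(ts$direction, "none")

  # doubling per time step: exact fold change, direction up
  dbl_fun <- function(s) {
    ti <- match(s$time_h, c(0, 4, 12, 24, 48, 72))
    matrix(10 + (ti - 1), 1, nrow(s), dimnames = list("P1", s$sample_id))
  }
  tc2 <- toy_timecourse(dbl_fun)
  ts2 <- trend_stats(tc2, "L1", "dr")
  expect_identical(ts2$direction, "up")
  expect_equal(ts2$fold_change, 2^5)
  expect_lt(ts2$anova_p, 1e-10)

  # planted FC = 4 with noise passes the joint criteria most of the time
  set.seed(65)
  ok <- replicate(10, {
    ramp_fun <- function(s) {
      base <- rnorm(1000, 18, 2)
      v <- matrix(base, 1000, nrow(s),
                  dimnames = list(sprintf("P%04d", 1:1000), s$sample_id))
      v[1, ] <- v[1, ] + 2 * s$time_h / 72      # log2(4) ramp
      v + rnorm(length(v), 0, 0.2)
    }
    tc3 <- toy_timecourse(ramp_fun, nl = 1, tnbc = TRUE)
    ts3 <- trend_stats(tc3, "L1", "dr")
    adj <- bh_adjust(ts3$anova_p)
    adj[1] < 0.05 && abs(ts3$log2_fc[1]) > 1 && ts3$direction[1] == "up"
  })
  expect_gte(mean(ok), 0.9)
})

test_that("opposite-dynamics selection recovers planted truth and rejects decoys", {
  sim <- simulate_timecourse(timecourse_sim_spec(
    n_proteins = 200L, n_monotone_per_drug = 8L, n_opposite = 10L,
    n_transient = 4L, n_ic50_per_drug = 3L, noise_sd = 0.05,
    target_missing_fraction = 0, seed = 66))
  sel <- opposite_dynamics_select(sim$experiment)
  expect_setequal(sel$proteins, sim$truth$opposite)
  # same-direction (monotone) proteins are never selected
  expect_length(intersect(sel$proteins, unlist(sim$truth$monotone)), 0L)

  # FC = 1.5 planted opposite effects fail criterion (ii)
  sim2 <- simulate_timecourse(timecourse_sim_spec(
    n_proteins = 100L, n_monotone_per_drug = 0L, n_opposite = 10L,
    opposite_fc = 1.5, n_transient = 0L, n_ic50_per_drug = 0L,
    noise_sd = 0.05, target_missing_fraction = 0, seed = 67))
  sel2 <- opposite_dynamics_select(sim2$experiment)
  expect_length(sel2$proteins, 0L)

  # intersect-across-drugs reading also recovers the planted set
  sel3 <- opposite_dynamics_select(sim$experiment,
                                   run_config(dyn_intersect_drugs = TRUE))
  expect_setequal(sel3$proteins, sim$truth$opposite)
})

test_that("shuffled subtype labels destroy opposite-dynamics hits", {
  sim <- simulate_timecourse(timecourse_sim_spec(
    n_proteins = 150L, n_monotone_per_drug = 5L, n_opposite = 10L,
    n_transient = 3L, n_ic50_per_drug = 3L, noise_sd = 0.2, seed = 68))
  tc <- sim$experiment
  set.seed(68)
  retained <- unlist(lapply(1:5, function(i) {
    lines <- unique(tc$samples$cell_line)
    new_tnbc <- stats::setNames(sample(tc$samples$tnbc[
      match(lines, tc$samples$cell_line)]), lines)
    s2 <- tc$samples
    s2$tnbc <- new_tnbc[s2$cell_line]
    tc2 <- timecourse_experiment(tc$values, s2, tc$time_points_h)
    sel <- opposite_dynamics_select(tc2)
    mean(sim$truth$opposite %in% sel$proteins)
  }))
  expect_lte(mean(retained), 0.05)
})

test_that("pathway consistency applies inclusive line-count thresholds", {
  # synthetic selection with controlled per-line calls: 5 TNBC + 4 non
  lines <- paste0("L", 1:9)
  tnbc <- stats::setNames(c(rep(TRUE, 5), rep(FALSE, 4)), lines)
  calls <- array(0L, c(3, 9, 1), dimnames = list(c("A", "B", "C"), lines, "dr"))
  calls["A", 1:5, 1] <- 1L; calls["A", 6:9, 1] <- -1L  # hit everywhere
  calls["B", 1:3, 1] <- 1L; calls["B", 6:7, 1] <- -1L  # 3/5 and 2/4 exactly
  calls["C", 1:2, 1] <- 1L; calls["C", 6:9, 1] <- -1L  # 2/5 TNBC -> fail
  selection <- structure(list(
    selected = data.frame(protein = c("A", "B", "C"), drug = "dr",
                          tnbc_direction = "up"),
    proteins = c("A", "B", "C"), calls = calls, tnbc = tnbc),
    class = "dynamics_selection")
  pw <- pathway_annotation(list(all = "A", boundary = "B", few = "C"))
  tab <- pathway_consistency(selection, pw)
  expect_true(tab$pass[tab$pathway == "all"])
  expect_true(tab$pass[tab$pathway == "boundary"])   # 3/5 and 2/4 inclusive
  expect_false(tab$pass[tab$pathway == "few"])       # 2 < 3 TNBC lines
  # empty annotation -> empty table
  empty <- pathway_consistency(selection,
                               pathway_annotation(stats::setNames(list(),
                                                                  character())))
  expect_equal(nrow(empty), 0L)
})

test_that("PDP detection applies the strict majority-fraction rule", {
  sim <- simulate_timecourse(timecourse_sim_spec(
    n_proteins = 200L, n_monotone_per_drug = 10L, n_opposite = 5L,
    n_transient = 8L, n_ic50_per_drug = 3L, noise_sd = 0.2,
    target_missing_fraction = 0, seed = 69))
  pdp <- pdp_detect(sim$experiment, "MK2206")
  mono <- sim$truth$monotone$MK2206
  expect_true(all(mono %in% pdp))                    # persistent recovered
  expect_length(intersect(sim$truth$transient, pdp), 0L)  # transient excluded
  counts <- attr(pdp, "dep_counts")
  used <- attr(pdp, "n_lines_used")
  expect_equal(used, 5L)
  # boundary: exactly 60% of lines is not "over 60%"
  at_60 <- names(counts)[counts == 3L]
  expect_length(intersect(at_60, pdp), 0L)
  in_all <- names(counts)[counts == used]
  expect_true(all(in_all %in% pdp))
})
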