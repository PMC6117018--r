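# Hand-checkable two-batch fixture: one gene, QC raw intensities
# {4, 6} in batch A and {2, 4} in batch B (log2 stored).
two_batch_qc <- function() {
  manual_cohort(
    study = matrix(c(3, 3, 3, 3), 1),
    study_batch = c("A", "A", "B", "B"),
    qc = log2(matrix(c(4, 6, 2, 4), 1)),
    qc_batch = c("A", "A", "B", "B")
  )
}

test_that("raw-scale QC factors are ratios of arithmetic means", {
  st <- compute_qc_stats(two_batch_qc())
  expect_equal(as.vector(st$qc_factor_raw), c(5 / 4, 3 / 4))
  # scale-free: multiplying all raw intensities by a constant (adding a
  # constant on the log2 scale) leaves the factors unchanged
  shifted <- two_batch_qc()
  shifted$values <- shifted$values + log2(37)
  expect_equal(compute_qc_stats(shifted)$qc_factor_raw, st$qc_factor_raw)
})

test_that("identical QCs across batches give unit factors", {
  coh <- manual_cohort(
    study = matrix(5, 2, 4), study_batch = c("A", "A", "B", "B"),
    qc = matrix(c(3, 3, 3, 3, 8, 8, 8, 8), 2, byrow = TRUE),
    qc_batch = c("A", "A", "B", "B")
  )
  st <- compute_qc_stats(coh)
  expect_equal(as.vector(st$qc_factor_raw), rep(1, 4))
  expect_equal(st$qc_batch_mean - st$qc_grand_mean,
               matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("log-scale and raw-scale factors differ by the geometric gap", {
  # batch-A raw replicates {4, 6}: log of the arithmetic-mean ratio vs
  # the difference of log2 means disagree unless replicates are equal
  expect_equal(log2(1.25), 0.321928, tolerance = 1e-6)
  expect_equal(mean(log2(c(4, 6))) - log2(4), 0.292481, tolerance = 1e-6)
  st <- compute_qc_stats(two_batch_qc())
  expect_false(isTRUE(all.equal(
    log2(st$qc_factor_raw[1, 1]),
    st$qc_batch_mean[1, 1] - st$qc_grand_mean[1]
  )))
  # with equal replicates within a batch the batch-level means agree
  # (log2 of the raw batch mean equals the mean of the log2 values);
  # the gap above comes entirely from within-batch replicate spread
  eq <- manual_cohort(
    study = matrix(1, 1, 4), study_batch = c("A", "A", "B", "B"),
    qc = log2(matrix(c(4, 4, 2, 2), 1)), qc_batch = c("A", "A", "B", "B")
  )
  se <- compute_qc_stats(eq)
  expect_equal(se$qc_batch_mean[1, ], c(A = 2, B = 1))
})

test_that("QC calibration removes batch shifts and is centering-idempotent", {
  coh <- small_cohort(n_genes = 40, seed = 3, batch_sizes = c(8, 7, 9),
                      latent_batch_sd = 0, qc_tech_sd = 0,
                      gene_sd_range = c(0, 0))
  # shift batch 2 (study and QCs alike) by +0.75 log2
  shift_cols <- coh$meta$batch == "b02"
  coh$values[, shift_cols] <- coh$values[, shift_cols] + 0.75
  st <- compute_qc_stats(coh)
  corrected <- apply_qc_calibration(coh, st, scale = "log")
  bm <- compute_batch_means(corrected, NULL)$batch_mean
  expect_lt(max(abs(bm - rowMeans(bm))), 1e-9)
  # re-computed log-scale factors on calibrated data are exactly zero
  st2 <- compute_qc_stats(corrected)
  expect_equal(st2$qc_batch_mean - st2$qc_grand_mean,
               matrix(0, 40, 3), tolerance = 1e-12, ignore_attr = TRUE)
  # unit factors leave the data untouched
  st_id <- st
  st_id$qc_batch_mean[] <- 0
  st_id$qc_grand_mean[] <- 0
  st_id$qc_factor_raw[] <- 1
  expect_equal(apply_qc_calibration(coh, st_id, "log")$values, coh$values)
  expect_equal(apply_qc_calibration(coh, st_id, "raw")$values, coh$values)
})

test_that("batch means and grand means follow the deconvolution identities", {
  coh <- manual_cohort(
    study = matrix(c(1, 1, 3, 3), 1), study_batch = c("A", "A", "B", "B"),
    qc = matrix(0, 1, 2), qc_batch = c("A", "B")
  )
  bm <- compute_batch_means(coh, NULL)
  expect_equal(as.vector(bm$batch_mean), c(1, 3))
  expect_equal(bm$grand_mean, 2, ignore_attr = TRUE)
  # per-gene centering invariant: mean over batches of deviations is zero
  coh2 <- small_cohort(n_genes = 30, seed = 8, batch_sizes = c(5, 6, 7))
  st <- compute_qc_stats(coh2)
  bm2 <- compute_batch_means(coh2, st)
  expect_lt(max(abs(rowMeans(bm2$batch_mean - bm2$grand_mean))), 1e-9)
  # folding the QC term into the mean equals calibrating first
  bm3 <- compute_batch_means(apply_qc_calibration(coh2, st, "log"), NULL)
  expect_equal(bm2$batch_mean, bm3$batch_mean, tolerance = 1e-12)
})

test_that("gamma matches hand arithmetic and recovers injected batch SD", {
  bmat <- matrix(c(1, 3, 0, 2), 2, byrow = TRUE)
  expect_equal(estimate_gamma(bmat, rowMeans(bmat)), 1)
  expect_equal(estimate_gamma(matrix(2, 3, 4), rep(2, 3)), 0)
  expect_error(estimate_gamma(matrix(1, 2, 1), c(1, 1)), "2 batches")
  # recovery of the injected latent batch SD (no QC term: the generator's
  # QCs share the exact latent offsets, so QC correction would absorb them)
  g <- 0.8
  est <- vapply(1:20, function(i) {
    coh <- small_cohort(n_genes = 150, seed = 100 + i,
                        batch_sizes = rep(18, 14),
                        latent_batch_sd = g, gene_sd_range = c(0.05, 0.05))
    bm <- compute_batch_means(coh, NULL)
    estimate_gamma(bm$batch_mean, bm$grand_mean)
  }, numeric(1))
  expect_lt(abs(mean(est) - g) / g, 0.1)
})

test_that("gamma under a null cohort shrinks as the sample size grows", {
  est <- vapply(c(20, 80, 320), function(m) {
    coh <- small_cohort(n_genes = 200, seed = m,
                        batch_sizes = rep(m / 4, 4),
                        latent_batch_sd = 0, gene_sd_range = c(0.2, 0.2))
    bm <- compute_batch_means(coh, NULL)
    estimate_gamma(bm$batch_mean, bm$grand_mean)
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("residual SDs use the population form and recover truth", {
  coh <- manual_cohort(
    study = matrix(c(4, 6), 1), study_batch = c("A", "A"),
    qc = matrix(0, 1, 1), qc_batch = "A"
  )
  expect_equal(estimate_residual_sd(coh, NULL), 1, ignore_attr = TRUE)
  flat <- manual_cohort(
    study = matrix(3, 1, 6), study_batch = rep(c("A", "B"), each = 3),
    qc = matrix(0, 1, 2), qc_batch = c("A", "B")
  )
  expect_equal(estimate_residual_sd(flat, NULL), 0, ignore_attr = TRUE)
  # recovery at the full-study subject count
  coh2 <- generate_base_cohort(cohort_config(n_genes = 400, seed = 17))
  st <- compute_qc_stats(coh2)
  est <- estimate_residual_sd(coh2, st)
  expect_lt(mean(abs(est - coh2$gene_sd) / coh2$gene_sd), 0.1)
})

test_that("calibration errors name degenerate inputs", {
  coh <- small_cohort(n_genes = 10, seed = 1, batch_sizes = c(4, 4))
  no_qc <- coh
  keep <- !no_qc$meta$is_qc | no_qc$meta$batch != "b01"
  no_qc$values <- no_qc$values[, keep]
  no_qc$meta <- no_qc$meta[keep, ]
  expect_error(compute_qc_stats(no_qc), "b01")
})

test_that("calibration stats serialize to TSV + JSON", {
  coh <- small_cohort(n_genes = 15, seed = 4, batch_sizes = c(5, 6))
  st <- calibrate_cohort(coh)
  tp <- tempfile(fileext = ".tsv")
  jp <- tempfile(fileext = ".json")
  write_calibration(st, tp, jp)
  long <- read.table(tp, sep = "\t", header = TRUE)
  expect_equal(nrow(long), 15 * 2)
  js <- jsonlite::read_json(jp)
  expect_equal(js$gamma, st$gamma, tolerance = 1e-12)
  expect_equal(js$m, sum(!coh$meta$is_qc))
})
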