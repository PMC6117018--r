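test_that("batch effect draws have the requested scale and determinism", {
  expect_equal(draw_batch_effects(0, 14, seed = 1), rep(0, 14))
  expect_identical(draw_batch_effects(2.72, 14, seed = 9),
                   draw_batch_effects(2.72, 14, seed = 9))
  set.seed(31)
  draws <- replicate(10000, draw_batch_effects(2.72, 14))
  expect_lt(abs(stats::sd(draws) - 2.72) / 2.72, 0.02)
})

test_that("treatment draws behave as a N(0, SD^2) subject covariate", {
  expect_equal(draw_treatment(50, 0, seed = 2), rep(0, 50))
  tr <- draw_treatment(251, 3, seed = 4)
  expect_lt(abs(stats::var(tr) - 9) / 9, 0.25)
  expect_false(identical(draw_treatment(20, 1, seed = 1),
                         draw_treatment(20, 1, seed = 2)))
})

test_that("injection is the identity under a fully null scenario", {
  coh <- small_cohort(n_genes = 60, seed = 6, batch_sizes = c(6, 7, 5))
  sc <- simulation_scenario(effect_sd = 0, gamma = 0, n_effect_genes = 0,
                            seed = 1)
  sim <- inject_effects(coh, sc, seed = 1)
  expect_equal(sim$values, coh$values)
})

test_that("injected components decompose exactly without the error arm", {
  coh <- small_cohort(n_genes = 80, seed = 12, batch_sizes = c(9, 8, 10))
  stats <- calibrate_cohort(coh)
  sc <- simulation_scenario(effect_sd = 1, gamma = 2.72,
                            n_effect_genes = 20, with_qc_term = TRUE,
                            seed = 5)
  sim <- inject_effects(coh, sc, stats, seed = 5)
  f <- factor(coh$meta$batch, levels = unique(coh$meta$batch))
  qterm <- (stats$qc_batch_mean - stats$qc_grand_mean)[, as.integer(f)]
  recon <- coh$values + qterm +
    matrix(sim$batch_effects[as.integer(f)], nrow(coh$values),
           ncol(coh$values), byrow = TRUE)
  st_idx <- which(!coh$meta$is_qc)
  recon[1:20, st_idx] <- recon[1:20, st_idx] +
    rep(sim$treatment, each = 20)
  expect_lt(max(abs(sim$values - recon)), 1e-9)
  expect_identical(sim$effect_genes, 1:20)
  # per-gene batch means of (s - x) on null genes equal r_j exactly
  delta <- (sim$values - coh$values - qterm)[21:80, st_idx]
  fb <- factor(coh$meta$batch[st_idx], levels = levels(f))
  for (j in seq_len(nlevels(fb))) {
    bj <- delta[, fb == levels(fb)[j], drop = FALSE]
    expect_lt(max(abs(bj - sim$batch_effects[j])), 1e-9)
  }
})

test_that("effect genes regressed with batch dummies recover unit slope", {
  coh <- small_cohort(n_genes = 10, seed = 21, batch_sizes = rep(18, 14))
  sc <- simulation_scenario(effect_sd = 1, n_effect_genes = 10, seed = 1)
  slopes <- unlist(lapply(1:50, function(i) {
    sim <- inject_effects(coh, sc, seed = i)
    fit_lm_batch_matrix(sim$study_values, sim$treatment, sim$batch)$slope
  }))
  expect_lt(abs(mean(slopes) - 1), 0.05)
})

test_that("sorting treatment across batches confounds it with batch", {
  set.seed(14)
  batch <- rep(sprintf("b%02d", 1:14), default_batch_sizes())
  tr <- rnorm(251, 0, 1)
  # f = 0: perfectly sorted, batch means strictly non-increasing
  t0 <- make_unbalanced(tr, batch, 0, seed = 1)
  bm <- tapply(t0, factor(batch, levels = unique(batch)), mean)
  expect_true(all(diff(bm) <= 0))
  expect_equal(sort(t0), sort(tr))
  # f = 0.2: ANOVA p-value numerically zero
  t2 <- make_unbalanced(tr, batch, 0.2, seed = 2)
  expect_lt(balance_anova(t2, batch), 1e-10)
  # f = 1: allocation is uniformly random; over many draws the largest
  # value lands in each batch proportionally to batch size
  counts <- table(factor(vapply(1:1000, function(i) {
    batch[which.max(make_unbalanced(tr, batch, 1))]
  }, ""), levels = unique(batch)))
  expect_gt(stats::chisq.test(counts, p = default_batch_sizes() / 251)$p.value,
            0.001)
})

test_that("balance ANOVA is calibrated and handles degenerate input", {
  expect_equal(balance_anova(rep(2, 10), rep(c("A", "B"), 5)), 1)
  expect_lt(balance_anova(c(0, 1e-4, 1, 1 + 1e-4), c("A", "A", "B", "B")),
            0.01)
  set.seed(77)
  ps <- replicate(1000, balance_anova(rnorm(60), rep(1:3, each = 20)))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cohort subsetting reproduces the reduced and grid designs", {
  coh <- generate_base_cohort(cohort_config(n_genes = 50, seed = 9))
  red <- subset_cohort(coh, "reduced", first_k_batches = 4)
  expect_equal(sum(!red$meta$is_qc), 85L)
  expect_equal(length(unique(red$meta$batch)), 4L)
  full <- subset_cohort(coh, "reduced", first_k_batches = 14)
  expect_identical(full$values, coh$values)
  expect_error(subset_cohort(coh, "reduced", first_k_batches = 15),
               "exceeds")
  grid <- subset_cohort(coh, "batch_size_grid", batch_size = 3)
  expect_equal(sum(!grid$meta$is_qc), 42L)
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(simulation_scenario(-1), "effect_sd")
  expect_error(simulation_scenario(1, gamma = -2), "gamma")
  expect_error(simulation_scenario(1, design = "unbalanced",
                                   random_fraction = 1.2),
               "random_fraction")
})
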