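#' Define a simulation scenario
#'
#' A scenario describes one cell of the benchmark: a treatment effect SD
#' acting on the first \code{n_effect_genes} genes, a batch-effect SD
#' \code{gamma}, optional per-observation residual error, the presence or
#' absence of the per-(gene, batch) QC offset term in the simulated data,
#' and the study design.
#'
#' @param effect_sd SD of the per-subject treatment variable (log2 units).
#'   The benchmark grid is \{0.1, 0.2, 0.3, 0.4, 0.5, 1, 3\}.
#' @param n_effect_genes Number of affected genes (default 500); always
#'   the first genes of the matrix.
#' @param gamma Batch-effect SD (default 2.72, the deconvolution estimate
#'   the simulator is parameterized by).
#' @param with_error Add per-observation noise \eqn{N(0, \sigma_{ei}^2)}
#'   using calibration residual SDs.
#' @param with_qc_term Include the QC offset term
#'   \eqn{q_{ij.} - \tau_{i..}} in the simulated values (the arm emulating
#'   data left on the uncalibrated scale). All models are fit to the
#'   simulated values directly in either arm.
#' @param design One of \code{"balanced"}, \code{"unbalanced"},
#'   \code{"reduced"}, \code{"batch_size_grid"}.
#' @param random_fraction For \code{"unbalanced"}: fraction of subjects
#'   re-randomized after sorting treatment across batches (default 0.2).
#' @param first_k_batches For \code{"reduced"}: number of leading batches
#'   kept (default 4).
#' @param batch_size For \code{"batch_size_grid"}: subjects per batch.
#' @param n_replicates Replicates for study runs (default 1000).
#' @param seed Master seed for the scenario; \code{NA} (default) lets the
#'   pipeline spawn one from its own master seed.
#' @return Object of class \code{sim_scenario}.
#' @export
simulation_scenario <- function(effect_sd,
                                n_effect_genes = 500L,
                                gamma = 2.72,
                                with_error = FALSE,
                                with_qc_term = FALSE,
                                design = c("balanced", "unbalanced",
                                           "reduced", "batch_size_grid"),
                                random_fraction = 0.2,
                                first_k_batches = 4L,
                                batch_size = 3L,
                                n_replicates = 1000L,
                                seed = NA_integer_) {
  design <- match.arg(design)
  if (effect_sd < 0) .stopf("simulation_scenario: effect_sd must be >= 0")
  if (gamma < 0) .stopf("simulation_scenario: gamma must be >= 0")
  if (random_fraction < 0 || random_fraction > 1) {
    .stopf("simulation_scenario: random_fraction must be in [0, 1]")
  }
  structure(
    list(effect_sd = effect_sd,
         n_effect_genes = as.integer(n_effect_genes),
         gamma = gamma,
         with_error = isTRUE(with_error),
         with_qc_term = isTRUE(with_qc_term),
         design = design,
         random_fraction = random_fraction,
         first_k_batches = as.integer(first_k_batches),
         batch_size = as.integer(batch_size),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Draw per-batch random batch effects
#'
#' \code{b} independent \eqn{N(0, \gamma^2)} draws, one shift per batch.
#'
#' @param gamma Batch-effect SD (>= 0).
#' @param n_batches Number of batches.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   \code{NULL}).
#' @return Numeric vector of length \code{n_batches}.
#' @export
draw_batch_effects <- function(gamma, n_batches, seed = NULL) {
  if (gamma < 0) .stopf("draw_batch_effects: gamma must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rnorm(n_batches, 0, gamma)
}

#' Draw the per-subject treatment variable
#'
#' One \eqn{N(0, SD^2)} value per subject. The same vector is both the
#' additive shift applied to effect genes (slope 1 by construction) and
#' the covariate of interest in every per-gene regression.
#'
#' @param m Number of subjects (>= 2).
#' @param sd Treatment SD (>= 0); 0 yields the null (zero) vector.
#' @param seed Optional integer seed.
#' @return Numeric vector of length \code{m}.
#' @export
draw_treatment <- function(m, sd, seed = NULL) {
  if (sd < 0) .stopf("draw_treatment: sd must be >= 0")
  if (m < 2) .stopf("draw_treatment: m must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rnorm(m, 0, sd)
}

#' Confound treatment with batch (unbalanced design)
#'
#' Sorts the treatment values in descending order and lays them across
#' batches in block order (the first batch receives the highest values,
#' the last the lowest), then re-randomizes a fraction
#' \code{random_fraction} of subjects by permuting their values among
#' themselves. Ties are broken by stable sort.
#'
#' @param treatment Per-subject treatment vector.
#' @param batch Per-subject batch labels (defines the block order through
#'   its order of first appearance).
#' @param random_fraction Fraction in [0, 1] re-randomized; 1 restores a
#'   fully random allocation, 0 leaves treatment perfectly sorted by batch.
#' @param seed Optional integer seed.
#' @return Treatment vector re-arranged against the fixed batch labels.
#' @export
make_unbalanced <- function(treatment, batch, random_fraction,
                            seed = NULL) {
  if (random_fraction < 0 || random_fraction > 1) {
    .stopf("make_unbalanced: random_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- length(treatment)
  f <- factor(batch, levels = unique(batch))
  ord <- order(as.integer(f))             # samples in batch-block order
  sorted <- sort(treatment, decreasing = TRUE, method = "radix")
  out <- numeric(m)
  out[ord] <- sorted
  n_rand <- round(random_fraction * m)
  if (n_rand >= 2) {
    idx <- sample.int(m, n_rand)
    out[idx] <- out[sample(idx)]
  }
  out
}

#' One-way ANOVA of treatment on batch
#'
#' F-test p-value measuring how confounded the treatment variable is with
#' batch membership. A constant treatment vector is reported as p = 1
#' (zero between-group variance).
#'
#' @param treatment Per-subject treatment vector.
#' @param batch Per-subject batch labels (>= 2 batches).
#' @return The ANOVA p-value.
#' @export
balance_anova <- function(treatment, batch) {
  f <- factor(batch)
  if (nlevels(f) < 2L) .stopf("balance_anova: need >= 2 batches")
  if (stats::var(treatment) == 0) return(1)
  fit <- stats::lm(treatment ~ f)
  tab <- stats::anova(fit)
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(p)) .stopf("balance_anova: F statistic undefined")
  p
}

#' Restrict or re-size a cohort
#'
#' \code{reduced}: keeps the study samples and QCs of the first
#' \code{first_k_batches} batches (under the default cohort, four batches
#' hold 85 subjects). \code{batch_size_grid}: regenerates the cohort with
#' the same number of batches but \code{batch_size} subjects in each.
#'
#' @param cohort An \code{expr_cohort}.
#' @param design \code{"reduced"} or \code{"batch_size_grid"}.
#' @param first_k_batches Leading batches to keep.
#' @param batch_size Subjects per batch for the grid design.
#' @return An \code{expr_cohort}.
#' @export
subset_cohort <- function(cohort, design = c("reduced", "batch_size_grid"),
                          first_k_batches = 4L, batch_size = 3L) {
  design <- match.arg(design)
  batches <- unique(cohort$meta$batch)
  if (design == "reduced") {
    k <- as.integer(first_k_batches)
    if (k > length(batches)) {
      .stopf("subset_cohort: first_k_batches (%d) exceeds batch count (%d)",
             k, length(batches))
    }
    keep <- cohort$meta$batch %in% batches[seq_len(k)]
    cohort$values <- cohort$values[, keep, drop = FALSE]
    cohort$meta <- cohort$meta[keep, , drop = FALSE]
    rownames(cohort$meta) <- NULL
    cohort
  } else {
    if (is.null(cohort$config)) {
      .stopf("subset_cohort: batch_size_grid needs a generator config")
    }
    cfg <- cohort$config
    cfg$batch_sizes <- rep(as.integer(batch_size),
                           length(cfg$batch_sizes))
    validate_cohort_config(cfg)
    generate_base_cohort(cfg)
  }
}

#' Inject batch, treatment and error effects into a base cohort
#'
#' Builds the simulated values
#' \deqn{s_{ijl} = x_{ijl} [+ (q_{ij.}-\tau_{i..})] + r_j + T_l 1\{i \le
#' n_{effect}\} [+ e_{ijl}],}
#' with \eqn{r_j \sim N(0,\gamma^2)} per batch, a shared per-subject
#' treatment vector \eqn{T \sim N(0, SD^2)} added with unit slope to the
#' first \code{n_effect_genes} genes, and optional per-observation error
#' with the calibration residual SDs. QC columns receive the batch shift
#' and QC offset of their batch (they travel with it) but no treatment or
#' subject-level error. Under the unbalanced design the treatment vector
#' is first confounded with batch via \code{\link{make_unbalanced}}.
#'
#' @param cohort Base \code{expr_cohort} (already reduced/re-sized if the
#'   scenario asks for it).
#' @param scenario A \code{sim_scenario}.
#' @param stats A \code{calibration_stats} aligned with \code{cohort};
#'   required when \code{with_qc_term} or \code{with_error} is set.
#' @param seed Optional integer seed for this replicate.
#' @return Object of class \code{sim_dataset}: \code{values} (full matrix,
#'   study + QC columns), \code{study_values}, \code{treatment},
#'   \code{batch} (study), \code{effect_genes}, \code{batch_effects},
#'   \code{scenario}.
#' @export
inject_effects <- function(cohort, scenario, stats = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- nrow(cohort$values)
  if (scenario$n_effect_genes > w) {
    .stopf("inject_effects: n_effect_genes (%d) exceeds gene count (%d)",
           scenario$n_effect_genes, w)
  }
  if ((scenario$with_qc_term || scenario$with_error) && is.null(stats)) {
    .stopf("inject_effects: scenario needs calibration stats")
  }
  batches <- unique(cohort$meta$batch)
  b <- length(batches)
  f_all <- factor(cohort$meta$batch, levels = batches)
  is_qc <- cohort$meta$is_qc
  m <- sum(!is_qc)

  r <- draw_batch_effects(scenario$gamma, b)
  tr <- draw_treatment(m, scenario$effect_sd)
  if (scenario$design == "unbalanced") {
    tr <- make_unbalanced(tr, cohort$meta$batch[!is_qc],
                          scenario$random_fraction)
  }

  s <- sweep(cohort$values, 2, r[as.integer(f_all)], "+")

  if (scenario$with_qc_term) {
    idx <- match(batches, stats$batches)
    if (anyNA(idx)) .stopf("inject_effects: stats missing a cohort batch")
    qterm <- stats$qc_batch_mean[, idx, drop = FALSE] - stats$qc_grand_mean
    s <- s + .expand_by_batch(qterm, f_all)
  }

  study_idx <- which(!is_qc)
  ng <- scenario$n_effect_genes
  if (ng > 0) {
    s[seq_len(ng), study_idx] <- s[seq_len(ng), study_idx] +
      rep(tr, each = ng)
  }
  if (scenario$with_error) {
    sd_e <- stats$residual_sd
    if (length(sd_e) != w) .stopf("inject_effects: residual_sd mismatch")
    s[, study_idx] <- s[, study_idx] +
      matrix(rnorm(w * m), w, m) * sd_e
  }

  structure(
    list(values = s,
         study_values = s[, study_idx, drop = FALSE],
         treatment = tr,
         batch = cohort$meta$batch[study_idx],
         effect_genes = seq_len(ng),
         batch_effects = stats::setNames(r, batches),
         scenario = scenario),
    class = "sim_dataset"
  )
}
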