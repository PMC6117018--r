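#' Label a scenario
#' @param scenario A \code{sim_scenario}.
#' @return A short human-readable id string.
#' @export
scenario_label <- function(scenario) {
  paste0("sd", scenario$effect_sd,
         "_gamma", scenario$gamma,
         "_", scenario$design,
         if (scenario$with_error) "_err" else "",
         if (scenario$with_qc_term) "_qc" else "")
}

# Materialize the cohort/calibration a scenario runs on (handles the
# reduced and batch-size-grid designs, which change the sample universe).
.scenario_universe <- function(cohort, stats, scenario) {
  if (scenario$design == "reduced") {
    sub <- subset_cohort(cohort, "reduced",
                         first_k_batches = scenario$first_k_batches)
    list(cohort = sub, stats = calibrate_cohort(sub))
  } else if (scenario$design == "batch_size_grid") {
    sub <- subset_cohort(cohort, "batch_size_grid",
                         batch_size = scenario$batch_size)
    list(cohort = sub, stats = calibrate_cohort(sub))
  } else {
    list(cohort = cohort, stats = stats)
  }
}

# Fit one method to one simulated dataset; returns per-gene p-values.
.fit_method <- function(method, sim) {
  Y <- sim$study_values
  tr <- sim$treatment
  switch(method,
    lm = fit_lm_matrix(Y, tr)$p_value,
    lm_batch = fit_lm_batch_matrix(Y, tr, sim$batch)$p_value,
    lmm = fit_lmm_matrix(Y, tr, sim$batch)$p_value,
    eb_lm = fit_lm_matrix(eb_batch_adjust(Y, sim$batch)$adjusted,
                          tr)$p_value,
    .stopf("unknown method '%s'", method)
  )
}

#' Run all replicates of one scenario
#'
#' For each replicate: draw fresh batch effects, treatment (and error)
#' under the scenario, fit each requested method per gene, BH-adjust at
#' \code{alpha} and score detections against the known effect set.
#' Replicate seeds are spawned deterministically from the scenario seed.
#' A method failing on a replicate is recorded as an NA row rather than
#' aborting the replicate.
#'
#' @param cohort Base \code{expr_cohort}.
#' @param stats Matching \code{calibration_stats} (recomputed internally
#'   for designs that change the sample universe).
#' @param scenario A \code{sim_scenario}.
#' @param methods Subset of \code{c("lmm", "lm", "lm_batch", "eb_lm")}.
#' @param alpha FDR threshold (default 0.05).
#' @param with_auc Also compute the ROC AUC per replicate (default TRUE).
#' @return Long data.frame: scenario, method, replicate, seed, tp, fp,
#'   mean_fdr_tp, mean_fdr_fp, auc.
#' @export
run_scenario <- function(cohort, stats, scenario,
                         methods = c("lmm", "lm", "lm_batch", "eb_lm"),
                         alpha = 0.05, with_auc = TRUE) {
  methods <- match.arg(methods, c("lmm", "lm", "lm_batch", "eb_lm"),
                       several.ok = TRUE)
  if (is.na(scenario$seed)) scenario$seed <- 1L
  uni <- .scenario_universe(cohort, stats, scenario)
  w <- nrow(uni$cohort$values)
  seeds <- .spawn_seeds(scenario$seed, scenario$n_replicates)
  label <- scenario_label(scenario)
  is_effect <- seq_len(w) %in% seq_len(scenario$n_effect_genes)
  rows <- vector("list", scenario$n_replicates * length(methods))
  k <- 0L
  for (rep_i in seq_len(scenario$n_replicates)) {
    sim <- inject_effects(uni$cohort, scenario, uni$stats,
                          seed = seeds[rep_i])
    for (mm in methods) {
      k <- k + 1L
      res <- tryCatch({
        p <- .fit_method(mm, sim)
        adj <- bh_adjust(p)
        sc <- score_detection(adj, sim$effect_genes, alpha)
        auc <- if (with_auc && any(is_effect) && !all(is_effect)) {
          roc_auc(p, is_effect)
        } else NA_real_
        data.frame(scenario = label, method = mm, replicate = rep_i,
                   seed = seeds[rep_i], tp = sc$tp, fp = sc$fp,
                   mean_fdr_tp = sc$mean_fdr_tp,
                   mean_fdr_fp = sc$mean_fdr_fp, auc = auc,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(scenario = label, method = mm, replicate = rep_i,
                   seed = seeds[rep_i], tp = NA_integer_,
                   fp = NA_integer_, mean_fdr_tp = NaN,
                   mean_fdr_fp = NaN, auc = NA_real_,
                   stringsAsFactors = FALSE)
      })
      rows[[k]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Assemble a full study configuration
#'
#' @param cohort A \code{\link{cohort_config}}.
#' @param scenarios Non-empty list of \code{\link{simulation_scenario}}s.
#' @param methods Non-empty subset of
#'   \code{c("lmm", "lm", "lm_batch", "eb_lm")}.
#' @param alpha FDR threshold in (0, 1).
#' @param output_dir Optional directory for TSV/JSON artifacts.
#' @param master_seed Integer; scenario seeds are spawned from it when a
#'   scenario does not set its own.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_config(),
                       scenarios,
                       methods = c("lmm", "lm", "lm_batch", "eb_lm"),
                       alpha = 0.05,
                       output_dir = NULL,
                       master_seed = 1L) {
  if (length(scenarios) == 0L) .stopf("run_config: no scenarios")
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  if (length(methods) == 0L) .stopf("run_config: no methods")
  methods <- match.arg(methods, c("lmm", "lm", "lm_batch", "eb_lm"),
                       several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) .stopf("run_config: alpha must be in (0,1)")
  structure(list(cohort = cohort, scenarios = scenarios,
                 methods = methods, alpha = alpha,
                 output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Run a complete benchmark study
#'
#' Generates the base cohort once, calibrates it, runs every scenario of
#' the configuration and averages replicates. With an \code{output_dir},
#' writes the per-replicate long table, the wide summary and a JSON run
#' manifest; re-running the same configuration reproduces the outputs
#' bit for bit.
#'
#' @param config A \code{\link{run_config}}.
#' @return List: \code{summary} (wide, one row per scenario),
#'   \code{by_method}, \code{replicates} (long), \code{gamma_hat}
#'   (calibration estimate of the base cohort).
#' @export
run_batch_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_base_cohort(config$cohort)
  stats <- calibrate_cohort(cohort)
  scen_seeds <- .spawn_seeds(config$master_seed,
                             length(config$scenarios))
  long <- list()
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    if (is.null(sc$seed) || is.na(sc$seed)) sc$seed <- scen_seeds[i]
    long[[i]] <- run_scenario(cohort, stats, sc, config$methods,
                              config$alpha)
  }
  long <- do.call(rbind, long)
  summ <- summarize_replicates(
    long, n_effect_genes = max(vapply(config$scenarios,
                                      `[[`, 1L, "n_effect_genes")))
  out <- list(summary = summ$wide, by_method = summ$by_method,
              replicates = long, gamma_hat = stats$gamma)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(long,
                       file.path(config$output_dir, "replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ$wide,
                       file.path(config$output_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      master_seed = config$master_seed,
      alpha = config$alpha,
      methods = config$methods,
      n_genes = config$cohort$n_genes,
      n_subjects = sum(config$cohort$batch_sizes),
      scenarios = lapply(config$scenarios, unclass),
      gamma_hat = stats$gamma
    )
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
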