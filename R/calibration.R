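#' Per-gene QC calibration statistics
#'
#' From the QC technical-replicate columns of a cohort, computes per gene
#' \eqn{i} and batch \eqn{j}: the batch QC mean on the log2 scale
#' \eqn{q_{ij.}}, the grand QC mean over all QC measurements
#' \eqn{\tau_{i..}} (mean over the n individual QC values, not over batch
#' means, so batches with a single QC weigh accordingly), and the
#' raw-intensity calibration factor
#' \deqn{QC_{ij} = \frac{\mathrm{mean}_k 2^{q_{ijk}}}{\mathrm{mean}_{jk} 2^{q_{ijk}}},}
#' the ratio of arithmetic means on the raw scale. The number of QC
#' replicates per batch defaults to 2 but any positive count per batch is
#' supported.
#'
#' @param cohort An \code{expr_cohort} with at least one QC per batch.
#' @return List of class \code{qc_stats}: \code{qc_batch_mean}
#'   (genes x batches, log2), \code{qc_grand_mean} (per gene, log2),
#'   \code{qc_factor_raw} (genes x batches, dimensionless), \code{batches},
#'   \code{qc_n} (QCs per batch).
#' @export
compute_qc_stats <- function(cohort) {
  qc <- qc_samples(cohort)
  if (ncol(qc$values) == 0L) .stopf("compute_qc_stats: cohort has no QCs")
  f <- factor(qc$batch, levels = unique(cohort$meta$batch))
  nk <- .group_sizes(f)
  if (any(nk == 0L)) {
    .stopf("compute_qc_stats: batch '%s' has zero QC samples",
           levels(f)[which(nk == 0L)[1]])
  }
  q_batch <- sweep(.group_sums(qc$values, f), 2, nk, "/")
  tau <- rowMeans(qc$values)
  raw <- 2^qc$values
  raw_batch <- sweep(.group_sums(raw, f), 2, nk, "/")
  qc_factor <- raw_batch / rowMeans(raw)
  structure(
    list(qc_batch_mean = q_batch, qc_grand_mean = tau,
         qc_factor_raw = qc_factor, batches = levels(f), qc_n = nk),
    class = "qc_stats"
  )
}

#' Apply QC calibration to an expression cohort
#'
#' On the log scale each value becomes \eqn{x_{ijl} - q_{ij.} + \tau_{i..}}
#' (a per-gene, per-batch re-centering toward the QC grand mean). On the
#' raw scale each intensity is divided by the multiplicative factor
#' \eqn{QC_{ij}} and re-logged. The log path is the pipeline default; the
#' two differ by the geometric-vs-arithmetic mean gap whenever QC
#' replicates disagree within a batch.
#'
#' @param cohort An \code{expr_cohort}.
#' @param stats A \code{qc_stats} computed on the same gene/batch universe.
#' @param scale \code{"log"} (default) or \code{"raw"}.
#' @return The cohort with calibrated \code{values}.
#' @export
apply_qc_calibration <- function(cohort, stats, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  f <- factor(cohort$meta$batch, levels = stats$batches)
  if (anyNA(f)) {
    .stopf("apply_qc_calibration: batch '%s' missing from stats",
           unique(cohort$meta$batch[is.na(f)])[1])
  }
  if (nrow(stats$qc_batch_mean) != nrow(cohort$values)) {
    .stopf("apply_qc_calibration: gene universe mismatch")
  }
  if (scale == "log") {
    adj <- .expand_by_batch(stats$qc_batch_mean, f) - stats$qc_grand_mean
    cohort$values <- cohort$values - adj
  } else {
    fac <- .expand_by_batch(stats$qc_factor_raw, f)
    cohort$values <- log2(2^cohort$values / fac)
  }
  cohort
}

#' Per-batch and grand means of QC-corrected study samples
#'
#' For every gene, the mean over each batch's study subjects of the
#' QC-corrected values \eqn{x_{ijl} - q_{ij.} + \tau_{i..}}, i.e.
#' \eqn{\mu_{ij.}}, and the unweighted mean of those batch means,
#' \eqn{\mu^*_{i..}}. The within-batch sum is divided by the per-batch
#' subject count (a true batch mean), which coincides with dividing by the
#' total subject count only under equal batch sizes; the batch-mean reading
#' is required for the grand mean and the batch-effect SD to be
#' interpretable.
#'
#' @param cohort An \code{expr_cohort} with study samples in every batch.
#' @param stats A \code{qc_stats}, or \code{NULL} to skip the QC term
#'   (plain batch means of the raw values).
#' @return List with \code{batch_mean} (genes x batches) and
#'   \code{grand_mean} (per gene).
#' @export
compute_batch_means <- function(cohort, stats = NULL) {
  st <- study_samples(cohort)
  f <- factor(st$batch, levels = unique(cohort$meta$batch))
  nj <- .group_sizes(f)
  if (any(nj == 0L)) {
    .stopf("compute_batch_means: batch '%s' has zero study samples",
           levels(f)[which(nj == 0L)[1]])
  }
  bm <- sweep(.group_sums(st$values, f), 2, nj, "/")
  if (!is.null(stats)) {
    bm <- bm - stats$qc_batch_mean + stats$qc_grand_mean
  }
  list(batch_mean = bm, grand_mean = rowMeans(bm))
}

#' Batch-effect standard deviation
#'
#' Population-form SD of the per-(gene, batch) means about the per-gene
#' grand means:
#' \deqn{\gamma = \sqrt{\frac{1}{bw}\sum_i\sum_j (\mu_{ij.}-\mu^*_{i..})^2}.}
#'
#' @param batch_mean Genes x batches matrix of batch means.
#' @param grand_mean Per-gene grand means.
#' @return Scalar \eqn{\gamma \ge 0} (log2 units).
#' @export
estimate_gamma <- function(batch_mean, grand_mean) {
  b <- ncol(batch_mean)
  if (is.null(b) || b < 2L) .stopf("estimate_gamma: need >= 2 batches")
  sqrt(mean((batch_mean - grand_mean)^2))
}

#' Per-gene residual standard deviation
#'
#' Residuals are QC-corrected study values minus their batch mean
#' \eqn{\mu_{ij.}}; the per-gene SD is the population SD over subjects of
#' those residuals (their mean subtracted, division by \eqn{m}). Centering
#' about batch means removes both batch and QC structure, so this SD can
#' later be injected on top of simulated batch effects without double
#' counting.
#'
#' @param cohort An \code{expr_cohort} with at least 2 study samples.
#' @param stats A \code{qc_stats}, or \code{NULL} for no QC term.
#' @return Numeric vector of per-gene residual SDs.
#' @export
estimate_residual_sd <- function(cohort, stats = NULL) {
  st <- study_samples(cohort)
  m <- ncol(st$values)
  if (m < 2L) .stopf("estimate_residual_sd: need >= 2 study samples")
  f <- factor(st$batch, levels = unique(cohort$meta$batch))
  bm <- compute_batch_means(cohort, stats)$batch_mean
  vals <- st$values
  if (!is.null(stats)) {
    vals <- vals - .expand_by_batch(
      stats$qc_batch_mean - stats$qc_grand_mean, f)
  }
  eps <- vals - .expand_by_batch(bm, f)
  eps <- eps - rowMeans(eps)
  sqrt(rowMeans(eps^2))
}

#' Full calibration of a cohort
#'
#' Convenience wrapper bundling \code{\link{compute_qc_stats}},
#' \code{\link{compute_batch_means}}, \code{\link{estimate_gamma}} and
#' \code{\link{estimate_residual_sd}} into one deconvolution-parameter
#' object used to drive the simulator.
#'
#' @param cohort An \code{expr_cohort}.
#' @param use_qc Apply the QC term when computing batch means and
#'   residuals (default \code{TRUE}).
#' @return Object of class \code{calibration_stats}: the \code{qc_stats}
#'   fields plus \code{batch_mean}, \code{grand_mean}, \code{gamma},
#'   \code{residual_sd}, \code{n_subjects}, \code{n_qcs}.
#' @export
calibrate_cohort <- function(cohort, use_qc = TRUE) {
  qs <- compute_qc_stats(cohort)
  st <- if (use_qc) qs else NULL
  bm <- compute_batch_means(cohort, st)
  structure(
    list(qc_batch_mean = qs$qc_batch_mean,
         qc_grand_mean = qs$qc_grand_mean,
         qc_factor_raw = qs$qc_factor_raw,
         batches = qs$batches,
         qc_n = qs$qc_n,
         batch_mean = bm$batch_mean,
         grand_mean = bm$grand_mean,
         gamma = estimate_gamma(bm$batch_mean, bm$grand_mean),
         residual_sd = estimate_residual_sd(cohort, st),
         n_subjects = sum(!cohort$meta$is_qc),
         n_qcs = sum(cohort$meta$is_qc)),
    class = "calibration_stats"
  )
}

#' Serialize calibration statistics
#'
#' Writes a long-format TSV (gene, batch, qc_batch_mean, qc_factor_raw,
#' batch_mean) plus a JSON scalar block (gamma, counts); and reads it back.
#'
#' @param stats A \code{calibration_stats}.
#' @param tsv_path,json_path File paths.
#' @return Invisibly, the paths.
#' @export
write_calibration <- function(stats, tsv_path, json_path) {
  w <- nrow(stats$qc_batch_mean)
  b <- length(stats$batches)
  long <- data.frame(
    gene = rep(rownames(stats$qc_batch_mean) %||% seq_len(w), b),
    batch = rep(stats$batches, each = w),
    qc_batch_mean = as.vector(stats$qc_batch_mean),
    qc_factor_raw = as.vector(stats$qc_factor_raw),
    batch_mean = as.vector(stats$batch_mean)
  )
  utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(gamma = stats$gamma, b = b, m = stats$n_subjects,
         w = w, n = stats$n_qcs),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv_path, json_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
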