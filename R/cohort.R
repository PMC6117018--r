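#' Default per-batch subject counts for the emulated cohort
#'
#' Subject counts for a 251-sample, 14-batch multi-batch microarray study.
#' The first four batches hold 85 subjects in total, so that restricting a
#' cohort to its first four batches reproduces the reduced-design sample
#' size used throughout the benchmark.
#'
#' @return Integer vector of length 14 summing to 251.
#' @export
default_batch_sizes <- function() {
  c(22L, 21L, 21L, 21L, rep(17L, 6), rep(16L, 4))
}

#' Configuration of a synthetic multi-batch expression cohort
#'
#' Describes the generative model for a base log2 expression matrix with
#' batch structure and quality-control (QC) technical replicates. Per gene
#' \eqn{i} a baseline mean \eqn{\mu_i} is drawn from a normal distribution
#' and a residual SD \eqn{\sigma_i} from a truncated log-normal; per
#' (gene, batch) a latent technical offset is drawn with SD
#' \code{latent_batch_sd}. Study samples are
#' \eqn{\mu_i + offset_{ij} + N(0, \sigma_i^2)}; QC columns replicate a
#' single shared reference subject \eqn{\mu_i^{QC} + offset_{ij} +
#' N(0, qc\_tech\_sd^2)}.
#'
#' @param n_genes Number of genes (probes). Default 27522, the probe count
#'   of the quantile-normalized arrays the generator emulates.
#' @param batch_sizes Integer vector of subjects per batch (length = number
#'   of batches). Default \code{\link{default_batch_sizes}}.
#' @param n_qc_per_batch QC technical replicates per batch (default 2).
#' @param deficient_qc_batch If \code{TRUE} (default) the last batch gets a
#'   single QC replicate, mirroring a study arm where one batch had only
#'   one usable QC (27 QCs in total under the defaults).
#' @param gene_mean_dist Length-2 numeric \code{c(mean, sd)} of the normal
#'   distribution of per-gene baseline log2 means. Default \code{c(7, 2)}.
#' @param gene_sd_dist Length-2 numeric \code{c(meanlog, sdlog)} of the
#'   log-normal distribution of per-gene residual SDs.
#'   Default \code{c(log(0.25), 0.5)}.
#' @param gene_sd_range Truncation bounds for the per-gene residual SDs
#'   (log2 units). Default \code{c(0.05, 1.0)}.
#' @param latent_batch_sd SD of the latent per-(gene, batch) technical
#'   offsets baked into the base data (log2 units). Default 0.3.
#' @param qc_tech_sd SD of QC technical replicate noise (log2 units).
#'   Default 0.1.
#' @param seed Integer seed; generation is deterministic given the config.
#'
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_genes = 27522,
                          batch_sizes = default_batch_sizes(),
                          n_qc_per_batch = 2,
                          deficient_qc_batch = TRUE,
                          gene_mean_dist = c(7, 2),
                          gene_sd_dist = c(log(0.25), 0.5),
                          gene_sd_range = c(0.05, 1.0),
                          latent_batch_sd = 0.3,
                          qc_tech_sd = 0.1,
                          seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    batch_sizes = as.integer(batch_sizes),
    n_qc_per_batch = as.integer(n_qc_per_batch),
    deficient_qc_batch = isTRUE(deficient_qc_batch),
    gene_mean_dist = as.numeric(gene_mean_dist),
    gene_sd_dist = as.numeric(gene_sd_dist),
    gene_sd_range = as.numeric(gene_sd_range),
    latent_batch_sd = as.numeric(latent_batch_sd),
    qc_tech_sd = as.numeric(qc_tech_sd),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_genes < 1L) .stopf("cohort_config: n_genes must be >= 1")
  if (length(cfg$batch_sizes) < 2L) {
    .stopf("cohort_config: batch_sizes must define >= 2 batches")
  }
  if (any(cfg$batch_sizes < 1L)) {
    .stopf("cohort_config: batch_sizes must all be >= 1")
  }
  if (cfg$n_qc_per_batch < 1L) {
    .stopf("cohort_config: n_qc_per_batch must be >= 1")
  }
  if (length(cfg$gene_mean_dist) != 2L || cfg$gene_mean_dist[2] < 0) {
    .stopf("cohort_config: gene_mean_dist must be c(mean, sd >= 0)")
  }
  if (length(cfg$gene_sd_dist) != 2L || cfg$gene_sd_dist[2] < 0) {
    .stopf("cohort_config: gene_sd_dist must be c(meanlog, sdlog >= 0)")
  }
  if (length(cfg$gene_sd_range) != 2L || any(cfg$gene_sd_range < 0) ||
      cfg$gene_sd_range[1] > cfg$gene_sd_range[2]) {
    .stopf("cohort_config: gene_sd_range must be 0 <= lo <= hi")
  }
  if (cfg$latent_batch_sd < 0) {
    .stopf("cohort_config: latent_batch_sd must be >= 0")
  }
  if (cfg$qc_tech_sd < 0) .stopf("cohort_config: qc_tech_sd must be >= 0")
  invisible(cfg)
}

qc_counts <- function(cfg) {
  b <- length(cfg$batch_sizes)
  k <- rep(cfg$n_qc_per_batch, b)
  if (cfg$deficient_qc_batch) k[b] <- 1L
  k
}

#' Generate a base synthetic cohort
#'
#' Draws a genes x (subjects + QCs) log2 expression matrix under the
#' generative model described in \code{\link{cohort_config}}. Column
#' metadata records batch, QC status and subject id; all QC columns share
#' one reference subject id.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return An object of class \code{expr_cohort}: list with \code{values}
#'   (numeric matrix, genes x samples), \code{gene_ids}, \code{meta}
#'   (data.frame: sample_id, batch, is_qc, subject_id), \code{gene_sd}
#'   (the true per-gene residual SDs; retained for oracle checks) and
#'   \code{config}.
#' @export
generate_base_cohort <- function(config) {
  validate_cohort_config(config)
  w <- config$n_genes
  sizes <- config$batch_sizes
  b <- length(sizes)
  k <- qc_counts(config)
  m <- sum(sizes)
  n <- sum(k)

  set.seed(config$seed)
  mu <- rnorm(w, config$gene_mean_dist[1], config$gene_mean_dist[2])
  sigma <- rlnorm(w, config$gene_sd_dist[1], config$gene_sd_dist[2])
  sigma <- pmin(pmax(sigma, config$gene_sd_range[1]), config$gene_sd_range[2])
  mu_qc <- rnorm(w, config$gene_mean_dist[1], config$gene_mean_dist[2])
  offsets <- matrix(rnorm(w * b, 0, config$latent_batch_sd), w, b)

  batch_ids <- sprintf("b%02d", seq_len(b))
  study_batch <- rep(batch_ids, sizes)
  qc_batch <- rep(batch_ids, k)

  study <- mu + offsets[, rep(seq_len(b), sizes), drop = FALSE] +
    matrix(rnorm(w * m, 0, 1), w, m) * sigma
  qc <- mu_qc + offsets[, rep(seq_len(b), k), drop = FALSE] +
    matrix(rnorm(w * n, 0, config$qc_tech_sd), w, n)

  values <- cbind(study, qc)
  gene_ids <- sprintf("g%05d", seq_len(w))
  rownames(values) <- gene_ids
  meta <- data.frame(
    sample_id = c(sprintf("s%03d", seq_len(m)), sprintf("qc%02d", seq_len(n))),
    batch = c(study_batch, qc_batch),
    is_qc = rep(c(FALSE, TRUE), c(m, n)),
    subject_id = c(sprintf("subj%03d", seq_len(m)), rep("qc_ref", n)),
    stringsAsFactors = FALSE
  )
  colnames(values) <- meta$sample_id

  structure(
    list(values = values, gene_ids = gene_ids, meta = meta,
         gene_sd = sigma, config = config),
    class = "expr_cohort"
  )
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf(
    "expr_cohort: %d genes x %d samples (%d study, %d QC) in %d batches\n",
    nrow(x$values), ncol(x$values), sum(!x$meta$is_qc), sum(x$meta$is_qc),
    length(unique(x$meta$batch))
  ))
  invisible(x)
}

#' Extract study (non-QC) columns of a cohort
#' @param cohort An \code{expr_cohort}.
#' @return List with \code{values} and \code{batch} for study samples.
#' @export
study_samples <- function(cohort) {
  keep <- !cohort$meta$is_qc
  list(values = cohort$values[, keep, drop = FALSE],
       batch = cohort$meta$batch[keep])
}

#' Extract QC columns of a cohort
#' @param cohort An \code{expr_cohort}.
#' @return List with \code{values} and \code{batch} for QC samples.
#' @export
qc_samples <- function(cohort) {
  keep <- cohort$meta$is_qc
  list(values = cohort$values[, keep, drop = FALSE],
       batch = cohort$meta$batch[keep])
}

#' Write / read a cohort as tab-delimited text
#'
#' The expression matrix is written as a TSV with a \code{gene_id} column
#' and one column per sample; metadata as a second TSV (sample_id, batch,
#' is_qc, subject_id). Round-trips are lossless to 6 decimals.
#'
#' @param cohort An \code{expr_cohort}.
#' @param matrix_path,meta_path Output/input file paths.
#' @return \code{write_cohort_tsv}: invisibly, the paths.
#'   \code{read_cohort_tsv}: an \code{expr_cohort} (without generator
#'   config or true gene SDs).
#' @export
write_cohort_tsv <- function(cohort, matrix_path, meta_path) {
  df <- data.frame(gene_id = cohort$gene_ids,
                   round(cohort$values, 6), check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(matrix_path, meta_path) {
  df <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  if (!identical(colnames(values), meta$sample_id)) {
    .stopf("read_cohort_tsv: matrix columns do not match metadata sample_id")
  }
  structure(
    list(values = values, gene_ids = df$gene_id, meta = meta,
         gene_sd = NULL, config = NULL),
    class = "expr_cohort"
  )
}
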