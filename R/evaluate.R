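#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, order-preserving and capped at 1. Non-finite
#' entries are excluded from the ranking (the effective test count is the
#' number of finite p-values), returned as \code{NaN}, and counted in an
#' attribute.
#'
#' @param p Vector of raw p-values in [0, 1] (NaN/NA allowed).
#' @return Adjusted p-values, same length and order; attribute
#'   \code{n_excluded} gives the count of non-finite inputs.
#' @export
bh_adjust <- function(p) {
  ok <- is.finite(p)
  out <- rep(NaN, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' True/false positive counts at an FDR threshold
#'
#' @param adjusted BH-adjusted p-values over the gene universe.
#' @param effect_genes Indices of the genes that truly carry an effect.
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return List: \code{tp}, \code{fp}, \code{mean_fdr_tp},
#'   \code{mean_fdr_fp} (mean adjusted p among the called true/false
#'   positives; \code{NaN} when a set is empty).
#' @export
score_detection <- function(adjusted, effect_genes, alpha = 0.05) {
  is_effect <- seq_along(adjusted) %in% effect_genes
  called <- !is.na(adjusted) & adjusted < alpha
  tp_set <- called & is_effect
  fp_set <- called & !is_effect
  list(tp = sum(tp_set), fp = sum(fp_set),
       mean_fdr_tp = if (any(tp_set)) mean(adjusted[tp_set]) else NaN,
       mean_fdr_fp = if (any(fp_set)) mean(adjusted[fp_set]) else NaN)
}

#' ROC area under the curve from p-values
#'
#' Ranks genes by ascending p-value (smaller p = more positive) and
#' computes the AUC as the normalized Mann-Whitney U statistic, ties
#' contributing 1/2. Non-finite p-values (failed fits) are ranked last.
#'
#' @param p Per-gene p-values.
#' @param labels Logical (or 0/1) effect indicator, aligned with \code{p}.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(p, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) .stopf("roc_auc: need both classes")
  score <- -p
  score[!is.finite(score)] <- -Inf
  r <- rank(score, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Association between principal components and batch
#'
#' PCA of the sample x gene matrix (genes centered, not scaled), followed
#' per component by the adjusted \eqn{R^2} of a one-way batch-factor fit
#' on the PC scores, \eqn{1 - (1 - R^2)(m - 1)/(m - b)}. Under no
#' association the expectation is the closed-form null
#' \eqn{-(b - 1)/(m - b)}, slightly negative; values near 1 indicate a
#' batch-dominated component.
#'
#' @param Y Numeric matrix, genes x samples.
#' @param batch Per-sample batch labels; needs more samples than batches.
#' @param n_pcs Number of leading components (default 5).
#' @return Numeric vector of adjusted R-squared values, one per PC.
#' @export
pc_batch_association <- function(Y, batch, n_pcs = 5L) {
  f <- factor(batch)
  m <- ncol(Y)
  b <- nlevels(f)
  if (m <= b) .stopf("pc_batch_association: need more samples than batches")
  n_pcs <- min(n_pcs, m - 1L, nrow(Y))
  pcs <- stats::prcomp(t(Y), center = TRUE, scale. = FALSE,
                       rank. = n_pcs)$x
  vapply(seq_len(ncol(pcs)), function(k) {
    summary(stats::lm(pcs[, k] ~ f))$adj.r.squared
  }, numeric(1))
}

#' Pairwise Pearson correlation among QC profiles
#'
#' All pairwise Pearson correlations between QC expression profiles
#' (columns). Technical replicates of one reference sample should be
#' nearly perfectly correlated once batch effects are removed.
#'
#' @param Yqc Numeric matrix, genes x QC samples (>= 2 columns).
#' @return List: \code{cor} (correlation matrix), \code{mean}, \code{min}
#'   over the off-diagonal pairs (zero-variance profiles give NaN pairs,
#'   excluded from the summaries, counted in \code{n_na_pairs}).
#' @export
qc_pearson_matrix <- function(Yqc) {
  if (ncol(Yqc) < 2L) .stopf("qc_pearson_matrix: need >= 2 QC columns")
  suppressWarnings(cm <- stats::cor(Yqc))
  off <- cm[lower.tri(cm)]
  list(cor = cm,
       mean = mean(off, na.rm = TRUE),
       min = suppressWarnings(min(off, na.rm = TRUE)),
       n_na_pairs = sum(is.na(off)))
}

#' Average per-replicate detection results
#'
#' Collapses a long per-replicate results table (columns: scenario label,
#' method, replicate, tp, fp, mean_fdr_tp, mean_fdr_fp, auc) into one row
#' per (scenario, method) of arithmetic means across replicates, then
#' reshapes to the benchmark's wide layout: one row per scenario with
#' TP/FP columns per method.
#'
#' @param results Long-format data.frame of per-replicate results.
#' @param n_effect_genes Known effect-gene count; rows violating
#'   \code{tp <= n_effect_genes} are a validation error.
#' @return List: \code{by_method} (one row per scenario x method, with
#'   \code{mean_tp}, \code{mean_fp}, \code{mean_fdrval_tp},
#'   \code{mean_fdrval_fp}, \code{auc}, \code{n_replicates}) and
#'   \code{wide} (one row per scenario, \code{<method>_tp} /
#'   \code{<method>_fp} columns).
#' @export
summarize_replicates <- function(results, n_effect_genes = NULL) {
  need <- c("scenario", "method", "replicate", "tp", "fp")
  if (!all(need %in% names(results))) {
    .stopf("summarize_replicates: missing columns: %s",
           paste(setdiff(need, names(results)), collapse = ", "))
  }
  if (!is.null(n_effect_genes) && any(results$tp > n_effect_genes)) {
    .stopf("summarize_replicates: tp exceeds n_effect_genes")
  }
  key <- interaction(results$scenario, results$method, drop = TRUE,
                     sep = "\r")
  agg <- function(x, f = mean) {
    as.vector(tapply(x, key, function(v) f(v[is.finite(v)])))
  }
  lv <- levels(key)
  parts <- strsplit(lv, "\r", fixed = TRUE)
  by_method <- data.frame(
    scenario = vapply(parts, `[`, "", 1),
    method = vapply(parts, `[`, "", 2),
    mean_tp = agg(results$tp),
    mean_fp = agg(results$fp),
    mean_fdrval_tp = if ("mean_fdr_tp" %in% names(results)) {
      agg(results$mean_fdr_tp)
    } else NA_real_,
    mean_fdrval_fp = if ("mean_fdr_fp" %in% names(results)) {
      agg(results$mean_fdr_fp)
    } else NA_real_,
    auc = if ("auc" %in% names(results)) agg(results$auc) else NA_real_,
    n_replicates = as.vector(tapply(results$replicate, key,
                                    function(v) length(unique(v)))),
    stringsAsFactors = FALSE
  )
  scen <- unique(by_method$scenario)
  methods <- unique(by_method$method)
  wide <- data.frame(scenario = scen, stringsAsFactors = FALSE)
  for (mm in methods) {
    sub <- by_method[by_method$method == mm, ]
    wide[[paste0(mm, "_tp")]] <- sub$mean_tp[match(scen, sub$scenario)]
    wide[[paste0(mm, "_fp")]] <- sub$mean_fp[match(scen, sub$scenario)]
  }
  list(by_method = by_method, wide = wide)
}
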