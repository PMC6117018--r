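# Small fixture builders shared across test files.

# Hand-built cohort from explicit study and QC matrices.
manual_cohort <- function(study, study_batch, qc, qc_batch) {
  study <- rbind(study)
  qc <- rbind(qc)
  w <- nrow(study)
  m <- ncol(study)
  n <- ncol(qc)
  values <- cbind(study, qc)
  gene_ids <- sprintf("g%03d", seq_len(w))
  rownames(values) <- gene_ids
  meta <- data.frame(
    sample_id = c(sprintf("s%02d", seq_len(m)), sprintf("qc%02d", seq_len(n))),
    batch = c(study_batch, qc_batch),
    is_qc = rep(c(FALSE, TRUE), c(m, n)),
    subject_id = c(sprintf("subj%02d", seq_len(m)), rep("qc_ref", n)),
    stringsAsFactors = FALSE
  )
  colnames(values) <- meta$sample_id
  structure(list(values = values, gene_ids = gene_ids, meta = meta,
                 gene_sd = NULL, config = NULL),
            class = "expr_cohort")
}

# Modest synthetic cohort for pipeline-level tests.
small_cohort <- function(n_genes = 300, seed = 11, ...) {
  generate_base_cohort(cohort_config(n_genes = n_genes, seed = seed, ...))
}
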