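# Internal helpers shared across modules.

# Column-group sums: Y (genes x samples) summed within levels of `f`.
# Returns genes x nlevels(f). Dense indicator multiply; batches are few.
.group_sums <- function(Y, f) {
  f <- as.factor(f)
  ind <- outer(as.integer(f), seq_len(nlevels(f)), "==") * 1
  out <- Y %*% ind
  colnames(out) <- levels(f)
  out
}

.group_sizes <- function(f) {
  f <- as.factor(f)
  as.vector(table(f))
}

# Expand a per-(gene, batch) matrix (w x b) to per-(gene, sample) (w x m).
.expand_by_batch <- function(M, f) {
  f <- as.factor(f)
  M[, as.integer(f), drop = FALSE]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Derive a stream of sub-seeds from one master seed, all < 2^31.
.spawn_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
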