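#' Remove estimated batch structure from an expression matrix
#'
#' Produces a batch-corrected copy of \code{Y} using the fitted parameters
#' of one of the three batch-aware models:
#' \describe{
#'   \item{\code{"lmm"}}{per gene, an intercept-only random-intercept
#'     model is fit by profile ML and the predicted random intercepts
#'     (shrunken batch means) are subtracted;}
#'   \item{\code{"lm_batch"}}{per gene, the fixed batch means are
#'     subtracted and re-centered so every gene keeps its overall mean;}
#'   \item{\code{"eb"}}{the parametric empirical-Bayes adjusted matrix of
#'     \code{\link{eb_batch_adjust}}.}
#' }
#'
#' @param Y Numeric matrix, genes x samples.
#' @param batch Per-sample batch labels.
#' @param method \code{"lmm"}, \code{"lm_batch"} or \code{"eb"}.
#' @return The corrected matrix, same dimensions and order.
#' @export
denoise_matrix <- function(Y, batch, method = c("lmm", "lm_batch", "eb")) {
  method <- match.arg(method)
  Y <- rbind(Y)
  f <- factor(batch, levels = unique(batch))
  if (method == "eb") {
    return(eb_batch_adjust(Y, batch)$adjusted)
  }
  if (method == "lm_batch") {
    nj <- .group_sizes(f)
    bm <- sweep(.group_sums(Y, f), 2, nj, "/")
    offsets <- bm - as.vector(bm %*% (nj / sum(nj)))
    return(Y - .expand_by_batch(offsets, f))
  }
  fit <- .lmm_intercept_blups(Y, batch)
  Y - .expand_by_batch(fit$blups, fit$f)
}
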