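#' Per-gene ordinary least squares across a matrix
#'
#' Fits \eqn{y = \beta_0 + \beta_1 T + \varepsilon} to every row of
#' \code{Y} by closed-form OLS, with a two-sided t test on \eqn{\beta_1}
#' (df = m - 2). Vectorized across genes; identical to looping
#' \code{lm(y ~ treatment)} row by row.
#'
#' @param Y Numeric matrix, genes x subjects.
#' @param treatment Per-subject covariate (non-constant, length >= 3).
#' @return data.frame with one row per gene: \code{intercept},
#'   \code{slope}, \code{se}, \code{p_value}, \code{residual_variance}.
#' @export
fit_lm_matrix <- function(Y, treatment) {
  Y <- rbind(Y)
  m <- ncol(Y)
  if (m < 3L) .stopf("fit_lm_matrix: need >= 3 subjects")
  if (length(treatment) != m) .stopf("fit_lm_matrix: length mismatch")
  if (stats::var(treatment) == 0) {
    .stopf("fit_lm_matrix: treatment covariate is constant")
  }
  tc <- treatment - mean(treatment)
  stt <- sum(tc^2)
  ybar <- rowMeans(Y)
  slope <- as.vector((Y %*% tc) / stt)
  intercept <- ybar - slope * mean(treatment)
  rss <- rowSums((Y - ybar)^2) - slope^2 * stt
  rss <- pmax(rss, 0)
  df <- m - 2L
  s2 <- rss / df
  se <- sqrt(s2 / stt)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- ifelse(slope[se == 0] == 0, 1, 0)
  data.frame(intercept = intercept, slope = slope, se = se,
             p_value = p, residual_variance = s2)
}

#' Per-gene OLS with batch fixed effects
#'
#' Fits \eqn{y = \beta_0 + \beta_1 T + batch + \varepsilon} per gene,
#' estimating \eqn{\beta_1} by the Frisch-Waugh-Lovell projection: both
#' \code{y} and \code{T} are centered within batch and the simple
#' regression of the residuals gives the same slope, standard error and t
#' test (df = m - b - 1) as the full fixed-effect fit. Equivalent to a
#' genewise one-way ANOVA adjustment for batch. A single batch degenerates
#' to \code{\link{fit_lm_matrix}}.
#'
#' @param Y Numeric matrix, genes x subjects.
#' @param treatment Per-subject covariate.
#' @param batch Per-subject batch labels.
#' @return data.frame as in \code{\link{fit_lm_matrix}} (the intercept is
#'   the grand intercept \eqn{\bar y - \beta_1 \bar T} after removing
#'   batch means).
#' @export
fit_lm_batch_matrix <- function(Y, treatment, batch) {
  Y <- rbind(Y)
  m <- ncol(Y)
  f <- factor(batch, levels = unique(batch))
  b <- nlevels(f)
  if (b < 2L) return(fit_lm_matrix(Y, treatment))
  if (m <= b + 1L) .stopf("fit_lm_batch_matrix: need m > b + 1")
  nj <- .group_sizes(f)
  tr_bm <- tapply(treatment, f, mean)
  tc <- treatment - tr_bm[as.integer(f)]
  stt <- sum(tc^2)
  if (stt <= .Machine$double.eps * sum(treatment^2)) {
    .stopf("fit_lm_batch_matrix: treatment collinear with batch")
  }
  bm <- sweep(.group_sums(Y, f), 2, nj, "/")
  Yc <- Y - .expand_by_batch(bm, f)
  slope <- as.vector((Yc %*% tc) / stt)
  rss <- pmax(rowSums(Yc^2) - slope^2 * stt, 0)
  df <- m - b - 1L
  s2 <- rss / df
  se <- sqrt(s2 / stt)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- ifelse(slope[se == 0] == 0, 1, 0)
  data.frame(intercept = rowMeans(Y) - slope * mean(treatment),
             slope = slope, se = se, p_value = p,
             residual_variance = s2)
}

#' Single-gene wrappers
#'
#' Convenience single-vector forms of the matrix fitters, returning one
#' gene fit as a list.
#'
#' @param y Expression values for one gene.
#' @param treatment Per-subject covariate.
#' @param batch Per-subject batch labels (for the batch-adjusted form).
#' @return List with \code{intercept}, \code{slope}, \code{se},
#'   \code{p_value}, \code{residual_variance} (and \code{batch_variance}
#'   for the mixed model).
#' @export
fit_gene_lm <- function(y, treatment) {
  as.list(fit_lm_matrix(matrix(y, nrow = 1), treatment)[1, ])
}

#' @rdname fit_gene_lm
#' @export
fit_gene_lm_batch <- function(y, treatment, batch) {
  as.list(fit_lm_batch_matrix(matrix(y, nrow = 1), treatment, batch)[1, ])
}

#' @rdname fit_gene_lm
#' @export
fit_gene_lm_on_adjusted <- function(y, treatment) {
  fit_gene_lm(y, treatment)
}
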