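# Random-intercept mixed model, fitted per gene by profiling the ML
# criterion over the variance ratio lambda = sigma_u^2 / sigma^2.
#
# For V = sigma^2 (I + lambda Z Z') with Z the batch indicator matrix,
# (I + lambda Z Z')^{-1} is block diagonal with blocks I - c_j J,
# c_j = lambda / (1 + lambda n_j), and log|I + lambda Z Z'| =
# sum_j log(1 + lambda n_j). Every quadratic form the profile deviance
# needs therefore reduces to per-batch sums, which are shared across the
# lambda search and computed once per matrix. This is what makes fitting
# tens of thousands of genes per replicate feasible.

# Design summaries shared by all genes.
.lmm_design <- function(treatment, batch) {
  f <- factor(batch, levels = unique(batch))
  nj <- .group_sizes(f)
  d <- list(f = f, nj = nj, b = nlevels(f), m = length(f))
  if (!is.null(treatment)) {
    d$st <- as.vector(tapply(treatment, f, sum))
    d$st_tot <- sum(treatment)
    d$stt <- sum(treatment^2)
  }
  d
}

# Per-gene summaries shared by all lambda evaluations.
.lmm_gene_stats <- function(Y, treatment, d) {
  g <- list(
    sy = .group_sums(Y, d$f),           # w x b batch sums of y
    sy_tot = rowSums(Y),
    syy = rowSums(Y^2)
  )
  if (!is.null(treatment)) g$syt_tot <- as.vector(Y %*% treatment)
  g
}

# Profile -2 log likelihood pieces at a lambda (scalar, or one per gene).
# Returns list(nll, slope, intercept, rss, a11, det).
.lmm_profile <- function(lambda, d, g, has_tr) {
  w <- length(g$sy_tot)
  if (length(lambda) == 1L) {
    cj <- lambda / (1 + lambda * d$nj)
    Cn <- matrix(cj, w, d$b, byrow = TRUE)
    logdet <- sum(log1p(lambda * d$nj))
  } else {
    Cn <- lambda / (1 + outer(lambda, d$nj))
    logdet <- rowSums(log1p(outer(lambda, d$nj)))
  }
  nsq <- matrix(d$nj, w, d$b, byrow = TRUE)
  a11 <- d$m - rowSums(Cn * nsq^2)
  b1 <- g$sy_tot - rowSums(Cn * nsq * g$sy)
  yvy <- g$syy - rowSums(Cn * g$sy^2)
  if (has_tr) {
    stm <- matrix(d$st, w, d$b, byrow = TRUE)
    a12 <- d$st_tot - rowSums(Cn * nsq * stm)
    a22 <- d$stt - rowSums(Cn * stm^2)
    b2 <- g$syt_tot - rowSums(Cn * stm * g$sy)
    det <- a11 * a22 - a12^2
    quad <- (a22 * b1^2 - 2 * a12 * b1 * b2 + a11 * b2^2) / det
    slope <- (a11 * b2 - a12 * b1) / det
    intercept <- (a22 * b1 - a12 * b2) / det
  } else {
    det <- a11
    quad <- b1^2 / a11
    slope <- rep(NA_real_, w)
    intercept <- b1 / a11
  }
  rss <- yvy - quad
  nll <- d$m * log(2 * pi * rss / d$m) + d$m + logdet
  bad <- !is.finite(nll) | rss <= 0 | det <= 0
  nll[bad] <- Inf
  list(nll = nll, slope = slope, intercept = intercept, rss = rss,
       a11 = a11, det = det, bad = bad)
}

# Per-gene minimizer of the profile deviance: coarse grid on lambda
# (including the sigma_u^2 = 0 boundary) followed by a vectorized
# golden-section refinement on log(lambda).
.lmm_optimize_lambda <- function(d, g, has_tr) {
  grid <- c(0, 10^seq(-6, 6, by = 0.5))
  nllg <- vapply(grid, function(l) .lmm_profile(l, d, g, has_tr)$nll,
                 numeric(length(g$sy_tot)))
  nllg <- rbind(nllg)
  idx <- max.col(-nllg, ties.method = "first")
  lo <- ifelse(idx <= 2L, 1e-8, grid[pmax(idx - 1L, 2L)])
  hi <- ifelse(idx >= length(grid), grid[length(grid)] * 100,
               grid[pmin(idx + 1L, length(grid))])
  lo <- log(lo); hi <- log(hi)
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- .lmm_profile(exp(x1), d, g, has_tr)$nll
  f2 <- .lmm_profile(exp(x2), d, g, has_tr)$nll
  for (it in seq_len(48L)) {
    left <- f1 < f2
    hi_n <- ifelse(left, x2, hi)
    lo_n <- ifelse(left, lo, x1)
    x1_n <- ifelse(left, hi_n - gr * (hi_n - lo_n), x2)
    x2_n <- ifelse(left, x1, lo_n + gr * (hi_n - lo_n))
    fnew <- .lmm_profile(exp(ifelse(left, x1_n, x2_n)), d, g, has_tr)$nll
    f1_n <- ifelse(left, fnew, f2)
    f2_n <- ifelse(left, f1, fnew)
    lo <- lo_n; hi <- hi_n; x1 <- x1_n; x2 <- x2_n; f1 <- f1_n; f2 <- f2_n
  }
  lam <- exp((lo + hi) / 2)
  # honor the boundary: keep sigma_u^2 = 0 whenever it is no worse
  nll_ref <- .lmm_profile(lam, d, g, has_tr)$nll
  nll0 <- nllg[, 1]
  ifelse(nll0 <= nll_ref + 1e-10, 0, lam)
}

#' Per-gene random-intercept linear mixed model
#'
#' Fits \eqn{y = \beta_0 + \beta_1 T + u_{batch} + \varepsilon},
#' \eqn{u_j \sim N(0, \sigma_u^2)}, to every row of \code{Y} by maximum
#' likelihood, profiling the deviance over the variance ratio
#' \eqn{\lambda = \sigma_u^2/\sigma^2} (grid plus golden-section search;
#' \eqn{\sigma_u^2 \ge 0} with the zero boundary allowed). Inference on
#' \eqn{\beta_1} is a Wald t test with df = m - 2; its standard error uses
#' the df-corrected residual variance RSS/(m - 2) so that a fit on the
#' \eqn{\sigma_u^2 = 0} boundary reduces exactly to ordinary least
#' squares. The reported variance components are the ML estimates
#' (RSS/m scale).
#'
#' @param Y Numeric matrix, genes x subjects.
#' @param treatment Per-subject covariate (non-constant).
#' @param batch Per-subject batch labels (>= 2 batches).
#' @return data.frame per gene: \code{intercept}, \code{slope}, \code{se},
#'   \code{p_value}, \code{batch_variance}, \code{residual_variance},
#'   \code{lambda}, \code{converged}. Degenerate genes get \code{NaN}
#'   p-values and \code{converged = FALSE}.
#' @export
fit_lmm_matrix <- function(Y, treatment, batch) {
  Y <- rbind(Y)
  m <- ncol(Y)
  if (length(treatment) != m || length(batch) != m) {
    .stopf("fit_lmm_matrix: dimension mismatch")
  }
  if (m <= 3L) .stopf("fit_lmm_matrix: need m > 3")
  if (stats::var(treatment) == 0) {
    .stopf("fit_lmm_matrix: treatment covariate is constant")
  }
  d <- .lmm_design(treatment, batch)
  if (d$b < 2L) .stopf("fit_lmm_matrix: need >= 2 batches")
  g <- .lmm_gene_stats(Y, treatment, d)
  lam <- .lmm_optimize_lambda(d, g, has_tr = TRUE)
  fin <- .lmm_profile(lam, d, g, has_tr = TRUE)
  df <- m - 2L
  se <- sqrt((fin$rss / df) * (fin$a11 / fin$det))
  tstat <- fin$slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  conv <- !fin$bad & is.finite(p)
  p[!conv] <- NaN
  data.frame(intercept = fin$intercept, slope = fin$slope, se = se,
             p_value = p,
             batch_variance = lam * fin$rss / m,
             residual_variance = fin$rss / m,
             lambda = lam, converged = conv)
}

#' @rdname fit_gene_lm
#' @export
fit_gene_lmm <- function(y, treatment, batch) {
  as.list(fit_lmm_matrix(matrix(y, nrow = 1), treatment, batch)[1, ])
}

# Intercept-only random-intercept fit; returns per-gene lambda and the
# shrunken batch means (BLUPs) used for mixed-model denoising.
.lmm_intercept_blups <- function(Y, batch) {
  Y <- rbind(Y)
  d <- .lmm_design(NULL, batch)
  g <- .lmm_gene_stats(Y, NULL, d)
  lam <- .lmm_optimize_lambda(d, g, has_tr = FALSE)
  fin <- .lmm_profile(lam, d, g, has_tr = FALSE)
  ybar_j <- sweep(g$sy, 2, d$nj, "/")
  resid_j <- ybar_j - fin$intercept
  shrink <- (lam * matrix(d$nj, length(lam), d$b, byrow = TRUE)) /
    (1 + outer(lam, d$nj))
  list(blups = shrink * resid_j, f = d$f, lambda = lam,
       intercept = fin$intercept)
}
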