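#' Remove column means from a window matrix
#'
#' The window (Casorati) matrix has one row per voxel and one column per
#' redundant measurement.  Each column is centred on its mean before PCA;
#' the means are kept so the reconstruction can restore them.
#'
#' @param X Numeric matrix, M voxels x N measurements, M >= 2.
#' @return A list with `Xc` (demeaned matrix) and `means` (length-N vector).
#' @export
demean_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    stop("need at least 2 rows (voxels) to remove column means")
  if (!all(is.finite(X)))
    stop("matrix contains non-finite entries")
  means <- colMeans(X)
  list(Xc = sweep(X, 2L, means, "-"), means = means)
}

#' Eigendecomposition of the window covariance
#'
#' Computes the eigenpairs of \eqn{(1/M) X_c^T X_c} for a demeaned M x N
#' window matrix with M >= N.  Eigenvalues are returned in ascending order;
#' tiny negative values from round-off are clipped to zero.
#'
#' @param Xc Demeaned matrix (output of [demean_columns()]), M >= N.
#' @return An object of class `eigen_spectrum`: list with `values`
#'   (ascending, length N), `vectors` (N x N orthonormal, columns match
#'   `values`), `M`, `N`, `gamma = N/M`.
#' @export
eigendecompose <- function(Xc) {
  Xc <- as.matrix(Xc)
  if (!all(is.finite(Xc)))
    stop("matrix contains non-finite entries")
  M <- nrow(Xc); N <- ncol(Xc)
  if (M < N)
    stop("require M >= N; transpose the window matrix first (M=", M, ", N=", N, ")")
  e <- eigen(crossprod(Xc) / M, symmetric = TRUE)
  vals <- rev(e$values)
  vals[vals < 0] <- 0
  structure(list(values = vals,
                 vectors = e$vectors[, N:1, drop = FALSE],
                 M = M, N = N, gamma = N / M),
            class = "eigen_spectrum")
}

new_classification <- function(method, spec, C, lambda_bar_c,
                               sigma2_mp = NA_real_, sigma2_max = NA_real_,
                               sigma2_prior = NA_real_, threshold = NA_real_) {
  structure(list(method = method,
                 n_noise = C,
                 n_signal = spec$N - C,
                 lambda_bar_c = lambda_bar_c,
                 sigma2_mp = sigma2_mp,
                 sigma2_max = sigma2_max,
                 sigma2_prior = sigma2_prior,
                 threshold = threshold,
                 snr_gain = if (C < spec$N) spec$N / (spec$N - C) else NA_real_,
                 M = spec$M, N = spec$N),
            class = "pca_classification")
}

#' @export
print.pca_classification <- function(x, ...) {
  cat(sprintf("PCA component classification [%s]\n", x$method))
  cat(sprintf("  noise components C = %d of N = %d (signal: %d)\n",
              x$n_noise, x$N, x$n_signal))
  if (is.finite(x$snr_gain))
    cat(sprintf("  nominal SNR gain N/(N-C) = %.3g\n", x$snr_gain))
  invisible(x)
}

#' MPPCA moment-matching classification
#'
#' Classifies the number C of eigenvalues carrying mostly noise without any
#' prior knowledge of the noise variance.  Starting from C = N, the largest
#' remaining eigenvalue is iteratively removed until the mean of the C
#' smallest eigenvalues satisfies
#' \eqn{\bar\lambda_C \ge \hat\sigma^2_{MP}}, where \eqn{\hat\sigma^2_{MP}}
#' is the bandwidth-derived variance [sigma2_from_width()] with
#' \eqn{\gamma_C = C/M}.  Ties are broken in favour of the larger C.
#'
#' This criterion assumes the noise eigenvalues follow the MP law, which
#' requires spatially uncorrelated noise; under correlated noise the
#' spectrum widens, \eqn{\hat\sigma^2_{MP}} is inflated, and C collapses.
#'
#' @param spec An `eigen_spectrum`.
#' @return A `pca_classification` with `method = "mppca"`.
#' @export
classify_mppca <- function(spec) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  lam <- spec$values
  for (C in seq(spec$N, 1L)) {
    lam_c <- lam[seq_len(C)]
    lbar <- mean(lam_c)
    s2mp <- sigma2_from_width(lam_c[C], lam_c[1L], C / spec$M)
    if (lbar >= s2mp)
      return(new_classification("mppca", spec, C, lbar, sigma2_mp = s2mp))
  }
  new_classification("mppca", spec, 0L, NA_real_)
}

#' General PCA (GPCA) classification from a noise-variance prior
#'
#' Selects the largest number C of smallest eigenvalues whose mean does not
#' exceed the externally estimated noise variance:
#' \eqn{C = \max\{c : \bar\lambda_c \le \hat\sigma^2_{prior}\}}.  The empty
#' set (c = 0) always satisfies the criterion, so C = 0 when even the
#' smallest eigenvalue exceeds the prior.  Because the eigenvalue mean is an
#' unbiased estimate of the post-reconstruction voxel noise variance
#' regardless of spatial noise correlations, this criterion remains correct
#' for correlated noise as long as the prior is accurate.
#'
#' @param spec An `eigen_spectrum`.
#' @param sigma2_prior A-priori noise variance (non-negative scalar).
#' @return A `pca_classification` with `method = "gpca"`.
#' @export
classify_gpca <- function(spec, sigma2_prior) {
  stopifnot(inherits(spec, "eigen_spectrum"),
            is.numeric(sigma2_prior), length(sigma2_prior) == 1L)
  if (!is.finite(sigma2_prior) || sigma2_prior < 0)
    stop("'sigma2_prior' must be a non-negative finite scalar")
  cm <- cumsum(spec$values) / seq_len(spec$N)
  ok <- which(cm <= sigma2_prior)
  C <- if (length(ok)) max(ok) else 0L
  new_classification("gpca", spec, C,
                     lambda_bar_c = if (C > 0) cm[C] else NA_real_,
                     sigma2_prior = sigma2_prior)
}

#' Threshold PCA (TPCA) classification from a noise-variance prior
#'
#' Inserts the prior into the MP upper bound to form the eigenvalue
#' threshold \eqn{\lambda_t = (1+\sqrt{\gamma})^2 \hat\sigma^2_{prior}} with
#' \eqn{\gamma = N/M}; eigenvalues strictly below the threshold are
#' classified as noise.  Equivalently, the largest retained noise eigenvalue
#' satisfies \eqn{\max(\lambda_C)/(1+\sqrt\gamma)^2 < \hat\sigma^2_{prior}}.
#' Only the upper edge of the spectrum matters, which makes the criterion
#' robust to prior overestimation and to moderate spectral widening.
#'
#' @inheritParams classify_gpca
#' @return A `pca_classification` with `method = "tpca"`; `threshold` holds
#'   \eqn{\lambda_t} and `sigma2_max` the implied variance estimate
#'   \eqn{\max(\lambda_C)/(1+\sqrt\gamma)^2}.
#' @export
classify_tpca <- function(spec, sigma2_prior) {
  stopifnot(inherits(spec, "eigen_spectrum"),
            is.numeric(sigma2_prior), length(sigma2_prior) == 1L)
  if (!is.finite(sigma2_prior) || sigma2_prior < 0)
    stop("'sigma2_prior' must be a non-negative finite scalar")
  lt <- (1 + sqrt(spec$gamma))^2 * sigma2_prior
  C <- sum(spec$values < lt)
  new_classification("tpca", spec, C,
                     lambda_bar_c = if (C > 0) mean(spec$values[seq_len(C)]) else NA_real_,
                     sigma2_max = if (C > 0) spec$values[C] / (1 + sqrt(spec$gamma))^2 else NA_real_,
                     sigma2_prior = sigma2_prior, threshold = lt)
}

#' Legacy fixed-threshold classification
#'
#' The original PCA-denoising rule: zero all eigenvalues below
#' \eqn{\tau = \upsilon^2 \sigma^2}, where \eqn{\upsilon} is an empirically
#' chosen correction factor.  Kept for comparison with the objective
#' criteria.
#'
#' @param spec An `eigen_spectrum`.
#' @param sigma2 Noise variance (non-negative scalar).
#' @param upsilon Positive correction factor.
#' @return A `pca_classification` with `method = "legacy"`.
#' @export
classify_legacy <- function(spec, sigma2, upsilon) {
  stopifnot(inherits(spec, "eigen_spectrum"),
            is.numeric(sigma2), length(sigma2) == 1L,
            is.numeric(upsilon), length(upsilon) == 1L)
  if (!is.finite(sigma2) || sigma2 < 0)
    stop("'sigma2' must be a non-negative finite scalar")
  if (!is.finite(upsilon) || upsilon <= 0)
    stop("'upsilon' must be a positive finite scalar")
  tau <- upsilon^2 * sigma2
  C <- sum(spec$values < tau)
  new_classification("legacy", spec, C,
                     lambda_bar_c = if (C > 0) mean(spec$values[seq_len(C)]) else NA_real_,
                     sigma2_prior = sigma2, threshold = tau)
}

#' MPPCA classification by explicit MP-spectrum fitting
#'
#' Alternative to the moment-matching rule of [classify_mppca()]: for each
#' candidate noise-set size C (scanning from N downwards) the MP density is
#' fitted to the C smallest eigenvalues by maximum likelihood over
#' \eqn{\sigma^2} at fixed \eqn{\gamma_C = C/M}; eigenvalues outside the
#' fitted support incur a heavy likelihood penalty.  The largest C is
#' accepted for which (i) the fitted support contains all C eigenvalues
#' within a small relative edge tolerance and (ii) the candidate spectrum
#' is consistent in shape with the fitted MP law, judged by a one-sample
#' Kolmogorov-Smirnov statistic against its 5% critical value
#' \eqn{1.358/\sqrt{C}}.  Much slower than moment matching; spectral
#' widening from spatially correlated noise breaks the shape test, so only
#' a few components are classified as noise in that regime.
#'
#' @param spec An `eigen_spectrum`.
#' @param edge_tol Relative tolerance on the fitted support edges when
#'   checking containment (default 0.05, accommodating finite-sample
#'   fluctuation of the extreme eigenvalues).
#' @return A `pca_classification` with `method = "mppca_slow"`; `sigma2_mp`
#'   holds the fitted variance.  If no candidate C is accepted the function
#'   returns C = 0.
#' @export
classify_mppca_slow <- function(spec, edge_tol = 0.05) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  lam <- spec$values
  any_fit <- FALSE
  for (C in seq(spec$N, 2L)) {
    lam_c <- lam[seq_len(C)]
    gc <- min(C / spec$M, 1)
    if (mean(lam_c) <= 0) next
    if ((lam_c[C] - lam_c[1L]) <= 1e-12 * max(lam_c[C], 1)) {
      # degenerate zero-bandwidth spectrum: perfect fit by construction
      return(new_classification("mppca_slow", spec, C, mean(lam_c),
                                sigma2_mp = mean(lam_c)))
    }
    nll <- function(s2) {
      p <- mp_params(s2, gc)
      d <- mp_pdf(pmax(lam_c, 0), p)
      # out-of-support points: penalised smoothly so the optimiser can move
      b <- mp_bounds(p)
      pen <- sum(pmax(lam_c - b$lambda_plus, 0) + pmax(b$lambda_minus - lam_c, 0)) /
        max(s2, .Machine$double.eps)
      -sum(log(pmax(d, 1e-300))) + 1e3 * pen
    }
    fit <- tryCatch(
      stats::optimize(nll, interval = c(mean(lam_c) / 4, 4 * mean(lam_c))),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_fit <- TRUE
    s2 <- fit$minimum
    b <- mp_bounds(mp_params(s2, gc))
    width <- b$lambda_plus - b$lambda_minus
    contained <- lam_c[C] <= b$lambda_plus + edge_tol * width &&
      lam_c[1L] >= b$lambda_minus - edge_tol * width
    if (contained && mp_ks_stat(lam_c, s2, gc) <= 1.358 / sqrt(C)) {
      return(new_classification("mppca_slow", spec, C, mean(lam_c), sigma2_mp = s2))
    }
  }
  if (!any_fit)
    warning("MP-spectrum fit failed for all candidate noise-set sizes; returning C = 0")
  new_classification("mppca_slow", spec, 0L, NA_real_)
}

# Kolmogorov-Smirnov distance between the empirical CDF of ascending
# eigenvalues and the MP CDF (grid trapezoid integration of the density)
mp_ks_stat <- function(lam_sorted, sigma2, gamma) {
  p <- mp_params(sigma2, gamma)
  b <- mp_bounds(p)
  grid <- seq(b$lambda_minus, b$lambda_plus, length.out = 2048L)
  dens <- mp_pdf(grid, p)
  cdf <- cumsum((dens[-1L] + dens[-length(dens)]) / 2) * diff(grid[1:2])
  cdf <- c(0, cdf / cdf[length(cdf)])
  Fmp <- stats::approx(grid, cdf, xout = lam_sorted, yleft = 0, yright = 1)$y
  n <- length(lam_sorted)
  max(abs(Fmp - (seq_len(n) - 0.5) / n)) + 0.5 / n
}

#' Reconstruct denoised signals from retained components
#'
#' Projects the demeaned window matrix onto the subspace of the N - C
#' largest-eigenvalue eigenvectors and restores the column means:
#' `means + Xc U_keep U_keep^T`.  `C = 0` returns the input unchanged;
#' `C = N` returns the column-mean matrix.
#'
#' @param Xc Demeaned M x N matrix.
#' @param spec The `eigen_spectrum` of `Xc`.
#' @param C Number of (smallest-eigenvalue) components to discard, 0..N.
#' @param means Length-N vector of column means to restore.
#' @return Denoised M x N matrix.
#' @export
reconstruct <- function(Xc, spec, C, means) {
  stopifnot(inherits(spec, "eigen_spectrum"))
  Xc <- as.matrix(Xc)
  N <- spec$N
  if (C < 0 || C > N) stop("'C' must lie in [0, N]")
  if (length(means) != N) stop("'means' must have length N")
  base <- matrix(means, nrow = nrow(Xc), ncol = N, byrow = TRUE)
  if (C == 0L) return(base + Xc)
  if (C == N)  return(base)
  U <- spec$vectors[, (C + 1L):N, drop = FALSE]
  base + Xc %*% U %*% t(U)
}

#' Nominal SNR gain from component removal
#'
#' Removing C of N components gives a nominal denoising gain of
#' `N / (N - C)` (as conventionally reported; whether a square root should
#' be applied depends on the SNR definition in use and is left to the
#' caller).
#'
#' @param N Total number of components (positive integer).
#' @param C Number removed, `0 <= C < N`.
#' @return The ratio `N / (N - C)`.
#' @export
snr_gain <- function(N, C) {
  stopifnot(is.numeric(N), is.numeric(C), length(N) == 1L, length(C) == 1L)
  if (N <= 0 || C < 0) stop("require N > 0 and C >= 0")
  if (C >= N) stop("SNR gain undefined for C = N (all components removed)")
  N / (N - C)
}
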