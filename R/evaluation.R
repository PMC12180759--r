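#' Denoising residuals
#'
#' Elementwise difference `denoised - raw`.  Structure-free, approximately
#' Gaussian residuals indicate noise removal without signal leakage;
#' near-zero residuals indicate failed denoising.
#'
#' @param denoised,raw Arrays of identical shape.
#' @return Array of the same shape.
#' @export
denoise_residuals <- function(denoised, raw) {
  if (!identical(dim(denoised) %||% length(denoised),
                 dim(raw) %||% length(raw)))
    stop("'denoised' and 'raw' must have identical shape")
  denoised - raw
}

#' Gaussian quantile-quantile comparison of residuals
#'
#' Standardises the sample and pairs its order statistics with standard-
#' normal quantiles at plotting positions (i - 0.5)/n; reports the Pearson
#' correlation of the pairs as a scalar normality summary (1 = perfectly
#' Gaussian-shaped).  Location/scale invariant by construction.
#'
#' @param residual_sample Numeric vector, at least 20 values with nonzero
#'   variance.
#' @return An object of class `qq_result`: list with `sample_quantiles`,
#'   `theoretical_quantiles`, and `correlation`.
#' @export
qq_gaussian <- function(residual_sample) {
  x <- as.numeric(residual_sample)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L)
    stop("need at least 20 finite residuals, got ", n)
  s <- stats::sd(x)
  if (s == 0)
    stop("residual sample has zero variance (degenerate denoising?)")
  sq <- sort((x - mean(x)) / s)
  tq <- stats::qnorm((seq_len(n) - 0.5) / n)
  structure(list(sample_quantiles = sq, theoretical_quantiles = tq,
                 correlation = stats::cor(sq, tq)),
            class = "qq_result")
}

#' Pooled eigenvalue spectrum over repeated noise instantiations
#'
#' Repeats phantom generation + classification `n_reps` times and pools the
#' eigenvalues classified as noise, to compare the empirical spectrum
#' against the MP law.  The reference MP parameters use the matched
#' eigenvalue variance (sigma2 = mean of the pooled eigenvalues) and the
#' window aspect ratio N/M.  Under uncorrelated noise the pooled support
#' matches the MP bounds; spatial correlation widens it beyond
#' \eqn{\lambda_+}.
#'
#' @param phantom_fun Function of one argument (an integer seed) returning
#'   the M x N window matrix of one noisy realisation.
#' @param classify_fun Function mapping an `eigen_spectrum` to a
#'   `pca_classification` (e.g. `classify_mppca`, or a closure fixing the
#'   prior for [classify_gpca()]/[classify_tpca()]).
#' @param n_reps Number of noise instantiations.
#' @param seed Base seed; repetition i uses `seed + i`.
#' @return An object of class `spectrum_ensemble`: list with
#'   `eigenvalue_samples` (pooled noise eigenvalues), `n_noise` (per-rep
#'   counts), `n_reps`, and `reference` (an [mp_params()]).
#' @export
spectrum_ensemble <- function(phantom_fun, classify_fun, n_reps, seed = 0L) {
  stopifnot(is.function(phantom_fun), is.function(classify_fun), n_reps >= 1)
  pooled <- vector("list", n_reps)
  counts <- integer(n_reps)
  gamma <- NULL
  for (i in seq_len(n_reps)) {
    X <- phantom_fun(seed + i)
    spec <- eigendecompose(demean_columns(X)$Xc)
    gamma <- spec$gamma
    cls <- classify_fun(spec)
    counts[i] <- cls$n_noise
    if (cls$n_noise > 0)
      pooled[[i]] <- spec$values[seq_len(cls$n_noise)]
  }
  lam <- unlist(pooled, use.names = FALSE)
  ref <- if (length(lam)) mp_params(mean(lam), gamma) else NULL
  structure(list(eigenvalue_samples = lam, n_noise = counts,
                 n_reps = n_reps, reference = ref),
            class = "spectrum_ensemble")
}

#' Root-mean-squared error maps
#'
#' RMSE of an estimate against ground truth, per voxel (over the
#' measurement dimension) and globally.
#'
#' @param estimate,truth Arrays of identical shape; the last dimension is
#'   treated as the measurement axis for the per-voxel map.
#' @return List with `global` (scalar) and `per_voxel` (array with the last
#'   dimension dropped).
#' @export
rmse_map <- function(estimate, truth) {
  if (!identical(dim(estimate) %||% length(estimate),
                 dim(truth) %||% length(truth)))
    stop("'estimate' and 'truth' must have identical shape")
  se <- (estimate - truth)^2
  nd <- length(dim(se))
  per_voxel <- if (nd >= 2L) sqrt(apply(se, seq_len(nd - 1L), mean)) else sqrt(se)
  list(global = sqrt(mean(se)), per_voxel = per_voxel)
}

#' Relative frequencies of preserved signal components
#'
#' Tabulates the `ncomp_map` of a [denoise_volume()] result (number of
#' signal components preserved at each window centre) as normalised
#' frequencies, optionally within a mask.
#'
#' @param ncomp_map 3D (or any) array of component counts.
#' @param mask Optional logical array of the same shape.
#' @return Named numeric vector of relative frequencies (names = component
#'   counts), summing to 1.
#' @export
ncomp_histogram <- function(ncomp_map, mask = NULL) {
  v <- if (is.null(mask)) ncomp_map else ncomp_map[as.logical(mask)]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("no component counts selected (empty mask?)")
  tab <- table(v)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}
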