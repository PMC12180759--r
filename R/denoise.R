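classify_spectrum <- function(spec, method, sigma2_prior = NULL, upsilon = NULL) {
  switch(method,
         mppca      = classify_mppca(spec),
         mppca_slow = classify_mppca_slow(spec),
         gpca       = classify_gpca(spec, sigma2_prior),
         tpca       = classify_tpca(spec, sigma2_prior),
         legacy     = classify_legacy(spec, sigma2_prior, upsilon),
         stop("unknown method '", method, "'"))
}

#' Denoise a single window matrix
#'
#' Runs the full per-window pipeline (demean, eigendecompose, classify,
#' reconstruct) on one M x N matrix.  If M < N the matrix is transposed,
#' the identical mathematics applied with the roles of voxels and
#' measurements exchanged (so gamma is always min/max), and the result
#' transposed back.
#'
#' @param X Window matrix, rows = voxels, columns = measurements.
#' @param method One of `"mppca"`, `"mppca_slow"`, `"gpca"`, `"tpca"`,
#'   `"legacy"`.
#' @param sigma2_prior Noise-variance prior; required for gpca/tpca/legacy.
#' @param upsilon Correction factor for `method = "legacy"`.
#' @return List with `denoised` (matrix like `X`), `classification`
#'   (a `pca_classification`), and `spectrum` (the `eigen_spectrum`).
#' @export
denoise_matrix <- function(X, method = c("mppca", "mppca_slow", "gpca", "tpca", "legacy"),
                           sigma2_prior = NULL, upsilon = NULL) {
  method <- match.arg(method)
  if (method %in% c("gpca", "tpca", "legacy") && is.null(sigma2_prior))
    stop("method '", method, "' requires a noise-variance prior")
  if (method == "legacy" && is.null(upsilon))
    stop("method 'legacy' requires the correction factor 'upsilon'")
  X <- as.matrix(X)
  flipped <- nrow(X) < ncol(X)
  if (flipped) X <- t(X)
  dm <- demean_columns(X)
  spec <- eigendecompose(dm$Xc)
  cls <- classify_spectrum(spec, method, sigma2_prior, upsilon)
  Y <- reconstruct(dm$Xc, spec, cls$n_noise, dm$means)
  if (flipped) Y <- t(Y)
  list(denoised = Y, classification = cls, spectrum = spec)
}

# enumerate clamped window start positions for one axis: one window centred
# on every voxel, shifted inward where the full window would not fit
axis_starts <- function(dim_len, w) {
  if (w > dim_len)
    stop("window size ", w, " exceeds volume extent ", dim_len)
  pmin(pmax(seq_len(dim_len) - (w - 1L) %/% 2L, 1L), dim_len - w + 1L)
}

#' Sliding-window PCA denoising with overcomplete averaging
#'
#' Slides a 2D (per-slice) or 3D window over the volume; each window
#' instance is denoised with [denoise_matrix()] and the overlapping
#' denoised estimates are combined by uniform averaging over all windows
#' covering each voxel.  One window is centred on every voxel, clamped
#' inward near edges so that every voxel is covered by at least one window.
#' GPCA/TPCA/legacy use, per window, the median of the noise-prior map over
#' the in-window voxels (the "effective" prior).  The procedure is fully
#' deterministic.
#'
#' @param data 4D array (x, y, z, measurements).  A 3D array is treated as
#'   a single-slice 4D volume.
#' @param window Integer vector of odd window dimensions, length 2
#'   (applied slice-wise) or 3.  See [parse_window()].
#' @param method Classification criterion, as in [denoise_matrix()].
#' @param noise_map A [noise_prior_map()] (or bare 3D/matrix array of
#'   voxelwise variances); required for gpca/tpca/legacy.
#' @param mask Optional logical/0-1 3D array; masked-out voxels are
#'   excluded from the per-window median prior (not from denoising).
#' @param upsilon Correction factor for `method = "legacy"`.
#' @return An object of class `denoise_result`: list with `denoised` (4D,
#'   same shape as input), `ncomp_map` (3D map of preserved signal
#'   components N-C at each window centre), `sigma2_map_used` (3D map of
#'   effective priors, NA for prior-free methods), and `residuals`
#'   (`denoised - data`).
#' @export
denoise_volume <- function(data, window, method = c("mppca", "mppca_slow", "gpca", "tpca", "legacy"),
                           noise_map = NULL, mask = NULL, upsilon = NULL) {
  method <- match.arg(method)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D (x, y, z, measurement) array")
  dims <- dim(data)
  window <- as.integer(window)
  if (!length(window) %in% 2:3 || any(window < 1L) || any(window %% 2L == 0L))
    stop("'window' must be 2 or 3 positive odd integers")
  if (length(window) == 2L) window <- c(window, 1L)
  needs_prior <- method %in% c("gpca", "tpca", "legacy")
  if (method == "legacy" && is.null(upsilon))
    stop("method 'legacy' requires the correction factor 'upsilon'")
  if (needs_prior) {
    if (is.null(noise_map))
      stop("method '", method, "' requires 'noise_map'")
    sig2 <- if (inherits(noise_map, "noise_prior_map")) noise_map$sigma2 else noise_map
    if (is.null(dim(sig2))) dim(sig2) <- c(length(sig2), 1L, 1L)
    if (length(dim(sig2)) == 2L) dim(sig2) <- c(dim(sig2), 1L)
    if (!all(dim(sig2) == dims[1:3]))
      stop("noise map dimensions do not match the volume")
  }
  if (!is.null(mask) && !all(dim(mask) == dims[1:3]))
    stop("mask dimensions do not match the volume")

  sx <- axis_starts(dims[1], window[1])
  sy <- axis_starts(dims[2], window[2])
  sz <- axis_starts(dims[3], window[3])

  acc <- array(0, dims)
  cov <- array(0, dims[1:3])
  ncomp <- array(NA_real_, dims[1:3])
  used <- array(NA_real_, dims[1:3])
  n_failed <- 0L

  for (cz in seq_len(dims[3])) for (cy in seq_len(dims[2])) for (cx in seq_len(dims[1])) {
    ix <- sx[cx]:(sx[cx] + window[1] - 1L)
    iy <- sy[cy]:(sy[cy] + window[2] - 1L)
    iz <- sz[cz]:(sz[cz] + window[3] - 1L)
    X <- matrix(data[ix, iy, iz, , drop = FALSE], ncol = dims[4])
    prior <- NULL
    if (needs_prior) {
      vals <- sig2[ix, iy, iz]
      if (!is.null(mask)) {
        keep <- as.logical(mask[ix, iy, iz])
        if (!any(keep))
          stop("window centred at (", cx, ",", cy, ",", cz, ") has no in-mask voxels")
        vals <- vals[keep]
      }
      prior <- stats::median(vals)
    }
    res <- tryCatch(denoise_matrix(X, method, sigma2_prior = prior, upsilon = upsilon),
                    error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] +
      array(res$denoised, c(window, dims[4]))
    cov[ix, iy, iz] <- cov[ix, iy, iz] + 1
    ncomp[cx, cy, cz] <- res$classification$n_signal
    if (needs_prior) used[cx, cy, cz] <- prior
  }
  if (n_failed > 0L)
    warning(n_failed, " window(s) failed to denoise and were skipped")
  if (any(cov == 0))
    stop("some voxels were covered by no successful window")
  denoised <- acc / array(rep(cov, dims[4]), dims)
  structure(list(denoised = denoised,
                 ncomp_map = ncomp,
                 sigma2_map_used = used,
                 residuals = denoised - data,
                 method = method, window = window,
                 n_failed_windows = n_failed),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("PCA denoising result [%s], window %s\n", x$method,
              paste(x$window, collapse = "x")))
  cat(sprintf("  volume: %s; preserved components (median over centres): %s\n",
              paste(dim(x$denoised), collapse = " x "),
              stats::median(x$ncomp_map, na.rm = TRUE)))
  invisible(x)
}
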