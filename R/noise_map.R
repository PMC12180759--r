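#' Voxelwise noise-variance map from repeated acquisitions
#'
#' Estimates the a-priori noise variance at each voxel as the unbiased
#' sample variance across r >= 2 repeated images acquired with identical
#' parameters (typically b = 0 volumes):
#' \eqn{\hat\sigma^2_{prior}(x,y,z) = \sum_i (S_i - \bar S)^2 / (r - 1)}.
#' Because the repetitions go through the same reconstruction as the data
#' to be denoised, the estimate captures the effective post-reconstruction
#' variance without any assumption on the spatial noise structure.
#'
#' @param b0_stack Either a 4D array (x, y, z, r) or a list of r identical-
#'   shape 3D (or 2D) arrays.
#' @param source_indices Optional record of which volumes of a larger
#'   series the repetitions were taken from.
#' @return An object of class `noise_prior_map`: list with `sigma2` (3D
#'   array of variances), `r`, and `source_indices`.
#' @export
variance_from_repeats <- function(b0_stack, source_indices = NULL) {
  if (is.list(b0_stack)) {
    shapes <- unique(lapply(b0_stack, function(v) dim(v) %||% length(v)))
    if (length(shapes) != 1L)
      stop("all repetitions must have the same shape")
    b0_stack <- array(unlist(b0_stack, use.names = FALSE),
                      c(shapes[[1L]], rep(1L, max(0L, 3L - length(shapes[[1L]]))),
                        length(b0_stack)))
  }
  nd <- length(dim(b0_stack))
  if (nd == 3L) dim(b0_stack) <- c(dim(b0_stack)[1:2], 1L, dim(b0_stack)[3])
  if (length(dim(b0_stack)) != 4L)
    stop("'b0_stack' must be a 4D array or list of equal-shape volumes")
  r <- dim(b0_stack)[4]
  if (r < 2L)
    stop("need at least 2 repetitions to estimate a variance, got ", r)
  m <- apply(b0_stack, 1:3, mean)
  ss <- apply(b0_stack^2, 1:3, sum)
  sigma2 <- (ss - r * m^2) / (r - 1)
  sigma2[sigma2 < 0] <- 0  # round-off guard
  structure(list(sigma2 = sigma2, r = r,
                 source_indices = source_indices %||% seq_len(r)),
            class = "noise_prior_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective per-window noise variance (median filter)
#'
#' The per-voxel variance estimates can be corrupted near tissue boundaries
#' by motion, pulsation or drift artifacts.  Taking the median over all
#' voxels of a sliding-window instance suppresses such outliers and
#' improves precision, assuming the noise level is roughly uniform within
#' the window.
#'
#' @param map A [variance_from_repeats()] result (or bare 3D array).
#' @param window Odd window dimensions (length 2 or 3), as in
#'   [denoise_volume()].
#' @param center Voxel index (length 3, 1-based) of the window centre;
#'   the window is clamped inward at volume edges.
#' @param mask Optional logical 3D array; masked-out voxels are excluded.
#' @return The median variance over the in-window voxels (scalar).
#' @export
window_median_sigma2 <- function(map, window, center, mask = NULL) {
  sig2 <- if (inherits(map, "noise_prior_map")) map$sigma2 else map
  if (length(dim(sig2)) == 2L) dim(sig2) <- c(dim(sig2), 1L)
  dims <- dim(sig2)
  window <- as.integer(window)
  if (length(window) == 2L) window <- c(window, 1L)
  center <- as.integer(center)
  if (length(center) == 2L) center <- c(center, 1L)
  idx <- lapply(1:3, function(a) {
    s <- min(max(center[a] - (window[a] - 1L) %/% 2L, 1L), dims[a] - window[a] + 1L)
    s:(s + window[a] - 1L)
  })
  vals <- sig2[idx[[1]], idx[[2]], idx[[3]]]
  if (!is.null(mask)) {
    keep <- as.logical(mask[idx[[1]], idx[[2]], idx[[3]]])
    vals <- vals[keep]
  }
  if (!length(vals))
    stop("window contains no (in-mask) voxels")
  stats::median(vals)
}

#' Volume-averaged noise variance
#'
#' Mean of the voxelwise variance map over all (or masked) voxels; this is
#' the single "exact" prior used in simulation experiments where noise is
#' uniform by construction.
#'
#' @param map A [variance_from_repeats()] result (or bare array).
#' @param mask Optional logical array of the same shape.
#' @return Scalar mean variance.
#' @export
global_mean_sigma2 <- function(map, mask = NULL) {
  sig2 <- if (inherits(map, "noise_prior_map")) map$sigma2 else map
  if (is.null(mask)) mean(sig2) else mean(sig2[as.logical(mask)])
}
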