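# deterministic quasi-uniform hemisphere point set (golden-angle spiral);
# the offset decorrelates the point sets of different shells
shell_directions <- function(n, shell_index = 1L) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5)) + 2 * pi * (shell_index - 1L) / 7
  r <- sqrt(pmax(1 - z^2, 0))
  unname(cbind(r * cos(phi), r * sin(phi), z))
}

#' Build a diffusion acquisition protocol
#'
#' Assembles b-values and unit gradient directions for `n_b0` unweighted
#' volumes followed by multi-shell diffusion weighting.  Directions are a
#' deterministic quasi-uniform (electrostatic-repulsion-style) hemisphere
#' point set, rotated per shell, so identical calls always give identical
#' protocols.  The default reproduces the 110-measurement protocol used by
#' the bundled phantom: 20 b = 0 volumes plus shells at b = 1, 2, 3
#' ms/um^2 with 30 directions each.
#'
#' @param n_b0 Number of b = 0 volumes.
#' @param shells List of `c(bval, n_dirs)` pairs (b in ms/um^2).
#' @return An object of class `dwi_protocol`: list with `bvals` (length N)
#'   and `bvecs` (N x 3; zero rows for b = 0).
#' @export
make_protocol <- function(n_b0 = 20L,
                          shells = list(c(1, 30), c(2, 30), c(3, 30))) {
  stopifnot(n_b0 >= 0, is.list(shells))
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, nrow = n_b0, ncol = 3)
  for (k in seq_along(shells)) {
    sh <- shells[[k]]
    stopifnot(length(sh) == 2L, sh[2] >= 1)
    bvals <- c(bvals, rep(sh[1], sh[2]))
    bvecs <- rbind(bvecs, shell_directions(as.integer(sh[2]), k))
  }
  if (length(bvals) < 1L) stop("protocol must contain at least one volume")
  structure(list(bvals = bvals, bvecs = bvecs), class = "dwi_protocol")
}

#' Axially symmetric diffusion tensor compartment
#'
#' @param ad Axial diffusivity (um^2/ms), `ad >= rd`.
#' @param rd Radial diffusivity (um^2/ms), non-negative.
#' @param direction Length-3 symmetry-axis vector (normalised internally).
#' @return An object of class `compartment_tensor`.
#' @export
compartment_tensor <- function(ad, rd, direction) {
  stopifnot(length(direction) == 3L, is.numeric(ad), is.numeric(rd))
  if (rd < 0 || ad < rd) stop("require ad >= rd >= 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector")
  structure(list(ad = ad, rd = rd, direction = direction / nrm),
            class = "compartment_tensor")
}

#' Multi-compartment diffusion signal
#'
#' Forward model \eqn{S(b, g) = \sum_j f_j \exp(-b\, g^T D_j g)} for a
#' mixture of axially symmetric tensors; \eqn{S(0) = 1} by construction
#' (fractions must sum to one).
#'
#' @param protocol A [make_protocol()] object.
#' @param compartments List of `list(fraction, tensor)` pairs, where
#'   `tensor` is a [compartment_tensor()].
#' @return Length-N signal vector.
#' @export
compartment_signal <- function(protocol, compartments) {
  stopifnot(inherits(protocol, "dwi_protocol"), is.list(compartments))
  fr <- vapply(compartments, function(cm) cm$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8)
    stop("compartment fractions must sum to 1 (got ", sum(fr), ")")
  S <- numeric(length(protocol$bvals))
  for (cm in compartments) {
    t <- cm$tensor
    stopifnot(inherits(t, "compartment_tensor"))
    g2 <- rowSums(protocol$bvecs^2)
    proj2 <- as.numeric(protocol$bvecs %*% t$direction)^2
    adc <- t$rd * g2 + (t$ad - t$rd) * proj2
    S <- S + cm$fraction * exp(-protocol$bvals * adc)
  }
  S
}

default_fractions <- function() {
  rbind(c(0.30, 0.35, 0.40),   # top portion row
        c(0.60, 0.65, 0.70),   # middle (crossing) portion row
        c(0.45, 0.50, 0.55))   # bottom portion row
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Default phantom fibre directions
#'
#' Six vertices of a regular icosahedron (unit-normalised), a maximally
#' spread deterministic direction set.  Rows 1-3 are used by the top
#' portions, rows 4-6 by the bottom portions, and middle (crossing)
#' portion i crosses row i with row i+3 orthogonalised against it.  A
#' well-spread three-dimensional set keeps all 8 signal eigenvalues of the
#' phantom well above the noise floor at the default SNR; coplanar
#' direction sets can make two portion contrasts nearly degenerate.
#'
#' @return 6 x 3 matrix of unit row vectors.
#' @export
default_fibre_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  unit_rows(rbind(c(0, 1, phi), c(1, phi, 0), c(phi, 0, 1),
                  c(0, -1, phi), c(-1, phi, 0), c(phi, 0, -1)))
}

#' Two-compartment crossing-fibre phantom (noise-free)
#'
#' Builds a square phantom divided into a 3 x 3 grid of equal portions.
#' Every voxel mixes two compartment types with fixed diffusivities
#' (AD1 = 1.8, RD1 = 0; AD2 = 1.5, RD2 = 0.5 um^2/ms); the mixing fraction
#' of type 1 is constant within a portion and differs between portions.
#' Top- and bottom-row portions contain a single fibre population (both
#' compartments aligned on one direction per portion); middle-row portions
#' contain two orthogonal crossing replicas of each compartment (four
#' sub-compartments).  The 9 portions have 9 distinct signal profiles, so
#' the demeaned voxels-by-measurements matrix has rank exactly 8.
#'
#' @param size Grid edge length, a multiple of 3 (default 12, giving 9
#'   portions of 4 x 4 voxels).
#' @param fractions 3 x 3 matrix of type-1 volume fractions (rows = portion
#'   rows top/middle/bottom).
#' @param fibre_directions 6 x 3 matrix of distinct fibre directions
#'   (normalised internally): rows 1-3 for the top portions, rows 4-6 for
#'   the bottom portions; middle portion i crosses row i with row i+3
#'   orthogonalised against it.  Default: [default_fibre_directions()].
#' @param protocol A [make_protocol()] object (default: the 110-measurement
#'   protocol).
#' @return An object of class `phantom_dataset` with `clean` (size x size x
#'   N array, S(b=0) = 1 everywhere), `protocol`, `fractions_grid`, and the
#'   per-portion directions; noise and correlation fields are unset until
#'   [add_noise()] / [zerofill_correlate()] are applied.
#' @export
build_phantom <- function(size = 12L, fractions = default_fractions(),
                          fibre_directions = default_fibre_directions(),
                          protocol = make_protocol()) {
  size <- as.integer(size)
  if (size %% 3L != 0L || size < 3L)
    stop("'size' must be a positive multiple of 3")
  stopifnot(is.matrix(fractions), all(dim(fractions) == c(3L, 3L)),
            all(fractions >= 0 & fractions <= 1),
            is.matrix(fibre_directions), all(dim(fibre_directions) == c(6L, 3L)))
  block <- size %/% 3L
  N <- length(protocol$bvals)
  dirs <- unit_rows(fibre_directions)
  clean <- array(NA_real_, c(size, size, N))
  portion_id <- matrix(NA_integer_, size, size)
  c1 <- function(d) compartment_tensor(1.8, 0.0, d)
  c2 <- function(d) compartment_tensor(1.5, 0.5, d)
  for (pr in 1:3) for (pc in 1:3) {
    f <- fractions[pr, pc]
    if (pr == 2L) {
      # crossing portions: orthogonal pair built from rows pc and pc+3
      da <- dirs[pc, ]
      db <- dirs[pc + 3L, ] - da * sum(da * dirs[pc + 3L, ])
      nb <- sqrt(sum(db^2))
      if (nb < 1e-8)
        stop("fibre_directions rows ", pc, " and ", pc + 3L,
             " are collinear; crossing portions need independent directions")
      db <- db / nb
      comps <- list(list(fraction = f / 2, tensor = c1(da)),
                    list(fraction = f / 2, tensor = c1(db)),
                    list(fraction = (1 - f) / 2, tensor = c2(da)),
                    list(fraction = (1 - f) / 2, tensor = c2(db)))
    } else {
      d <- if (pr == 1L) dirs[pc, ] else dirs[pc + 3L, ]
      comps <- list(list(fraction = f, tensor = c1(d)),
                    list(fraction = 1 - f, tensor = c2(d)))
    }
    S <- compartment_signal(protocol, comps)
    rows <- ((pr - 1L) * block + 1L):(pr * block)
    cols <- ((pc - 1L) * block + 1L):(pc * block)
    for (i in rows) for (j in cols) clean[i, j, ] <- S
    portion_id[rows, cols] <- (pr - 1L) * 3L + pc
  }
  structure(list(clean = clean, noisy = NULL,
                 processed_clean = NULL, processed_noisy = NULL,
                 protocol = protocol, sigma_true = NULL,
                 fractions_grid = fractions, fibre_directions = dirs,
                 portion_id = portion_id, n_zero_cols = 0L, seed = NULL),
            class = "phantom_dataset")
}

#' Corrupt signals with synthetic noise
#'
#' Adds iid Gaussian noise (`S + e`, `e ~ N(0, sigma^2)`) or Rician noise
#' (`|S + e1 + i e2|` with independent Gaussian real/imaginary parts) to a
#' signal array or to the `clean` field of a [build_phantom()] dataset.
#' With the phantom normalised to S(b=0) = 1, an SNR of 30 corresponds to
#' `sigma = 1/30`.
#'
#' @param x A numeric array, or a `phantom_dataset`.
#' @param sigma Noise standard deviation (signal units), `sigma >= 0`.
#' @param model `"gaussian"` or `"rician"`.
#' @param seed Integer seed; a fixed seed reproduces the noise
#'   bit-identically.
#' @return Same type as `x`; for a dataset, the `noisy`, `sigma_true`,
#'   `noise_model` and `seed` fields are filled in.
#' @export
add_noise <- function(x, sigma, model = c("gaussian", "rician"), seed = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (inherits(x, "phantom_dataset")) {
    x$noisy <- add_noise(x$clean, sigma, model, seed)
    x$sigma_true <- sigma
    x$noise_model <- model
    x$seed <- seed
    return(x)
  }
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(x)
  n <- length(x)
  if (model == "gaussian") {
    x + array(stats::rnorm(n, sd = sigma), dim(x) %||% n)
  } else {
    re <- x + stats::rnorm(n, sd = sigma)
    im <- stats::rnorm(n, sd = sigma)
    array(sqrt(re^2 + im^2), dim(x) %||% n)
  }
}

# 1-based unshifted-FFT column indices of the n_zero highest-|frequency|
# spatial-frequency columns (Nyquist first, then +/- pairs outward-in;
# negative member first when n_zero is even).  For odd n_zero the set is
# conjugate-symmetric, so the zero-filled image is exactly real.
zerofill_cols <- function(n, n_zero) {
  if (n_zero == 0L) return(integer(0))
  freq <- c(0:(n %/% 2L), if (n %% 2L == 0L) -((n %/% 2L - 1L):1L) else -((n %/% 2L):1L))
  ord <- order(-abs(freq), freq)
  sort(ord[seq_len(n_zero)])
}

# exact per-voxel variance transfer of zerofill + real part for real input:
# column k of the image spectrum survives with amplitude
# (kept(k) + kept(-k)) / 2
zerofill_variance_factor <- function(n, n_zero) {
  zeroed <- logical(n)
  zeroed[zerofill_cols(n, n_zero)] <- TRUE
  idx0 <- seq_len(n) - 1L
  conj_idx <- ((n - idx0) %% n) + 1L
  a <- (as.numeric(!zeroed) + as.numeric(!zeroed[conj_idx])) / 2
  mean(a^2)
}

#' Induce spatially correlated noise by k-space zero-filling
#'
#' Per volume: 2D FFT, zero the `n_zero_cols` highest-spatial-frequency
#' k-space columns (emulating the zero-padding of partial-Fourier-style
#' reconstructions), inverse FFT, real part.  The zeroed set is chosen
#' conjugate-symmetrically (Nyquist column first, then +/- frequency pairs
#' inward), so for odd `n_zero_cols` the output is exactly real and,
#' applied to pure noise, the per-voxel variance is reduced exactly by the
#' fraction of zeroed columns (Parseval: 9/12 when zeroing 3 of 12) while
#' spatial correlation is introduced along the zero-filled axis.  The
#' operation is linear, so applying it separately to clean and noisy data
#' keeps `processed_noisy - processed_clean` equal to processed noise.
#'
#' @param x A 3D array (x, y, measurements), a single matrix, or a
#'   `phantom_dataset` (then both `clean` and `noisy` are processed into
#'   `processed_clean` / `processed_noisy`).
#' @param n_zero_cols Number of k-space columns to zero (default 3, the
#'   value used with 12 x 12 phantoms; use 16 for 66 x 66 phantoms to keep
#'   the zero-filling factor similar).
#' @return Same type as `x`.
#' @export
zerofill_correlate <- function(x, n_zero_cols = 3L) {
  n_zero_cols <- as.integer(n_zero_cols)
  stopifnot(n_zero_cols >= 0L)
  if (inherits(x, "phantom_dataset")) {
    x$processed_clean <- zerofill_correlate(x$clean, n_zero_cols)
    if (!is.null(x$noisy))
      x$processed_noisy <- zerofill_correlate(x$noisy, n_zero_cols)
    x$n_zero_cols <- n_zero_cols
    return(x)
  }
  one <- function(img, cols) {
    F <- stats::fft(img)
    F[, cols] <- 0
    Re(stats::fft(F, inverse = TRUE)) / length(F)
  }
  nc <- if (is.matrix(x)) ncol(x) else dim(x)[2]
  if (n_zero_cols == 0L) return(x)
  if (n_zero_cols >= nc)
    stop("cannot zero ", n_zero_cols, " of ", nc, " k-space columns")
  cols <- zerofill_cols(nc, n_zero_cols)
  if (is.matrix(x)) return(one(x, cols))
  stopifnot(length(dim(x)) == 3L)
  out <- x
  for (k in seq_len(dim(x)[3])) out[, , k] <- one(x[, , k], cols)
  out
}

#' Induce spatially correlated noise by Gaussian smoothing
#'
#' Per-volume 2D Gaussian convolution (separable kernel, reflective
#' boundaries); `fwhm = 0` is the identity.  An alternative correlation
#' mechanism to [zerofill_correlate()], emulating smoothing applied during
#' image reconstruction.
#'
#' @param x A 3D array (x, y, measurements), a matrix, or a
#'   `phantom_dataset`.
#' @param fwhm Kernel full width at half maximum in voxels.
#' @return Same type as `x`.
#' @export
smooth_correlate <- function(x, fwhm) {
  stopifnot(is.numeric(fwhm), length(fwhm) == 1L, fwhm >= 0)
  if (inherits(x, "phantom_dataset")) {
    x$processed_clean <- smooth_correlate(x$clean, fwhm)
    if (!is.null(x$noisy))
      x$processed_noisy <- smooth_correlate(x$noisy, fwhm)
    x$smooth_fwhm <- fwhm
    return(x)
  }
  if (fwhm == 0) return(x)
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-rad, rad), sd = sd)
  k <- k / sum(k)
  conv1 <- function(v) {
    # reflective padding
    n <- length(v)
    pad <- c(v[pmin(rad, n):1], v, v[n:max(1L, n - rad + 1L)])
    stats::filter(pad, k, sides = 2)[(rad + 1L):(rad + n)]
  }
  one <- function(img) {
    img <- apply(img, 2L, conv1)
    t(apply(img, 1L, conv1))
  }
  if (is.matrix(x)) return(one(x))
  stopifnot(length(dim(x)) == 3L)
  out <- x
  for (kk in seq_len(dim(x)[3])) out[, , kk] <- one(x[, , kk])
  out
}

#' Effective noise variance of a phantom dataset
#'
#' True per-voxel variance of the noise actually present in the denoiser
#' input: `sigma_true^2`, reduced by the exact Parseval transfer factor of
#' the zero-filling operation (`1 - n_zero_cols/size` for a conjugate-
#' symmetric zeroed set, e.g. 9/12 when 3 of 12 columns are zeroed).
#'
#' @param dataset A `phantom_dataset`.
#' @return Scalar variance.
#' @export
effective_sigma2 <- function(dataset) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  if (is.null(dataset$sigma_true))
    stop("dataset has no noise added yet")
  s2 <- dataset$sigma_true^2
  if (!is.null(dataset$n_zero_cols) && dataset$n_zero_cols > 0L)
    s2 <- s2 * zerofill_variance_factor(dim(dataset$clean)[2], dataset$n_zero_cols)
  s2
}

#' Perturbed noise-prior values for robustness sweeps
#'
#' Multiplies the dataset's true effective noise variance by each factor,
#' yielding the prior values for misestimation-robustness curves (for
#' example factors from 0.5, a 50% underestimate, to 4, a 400%
#' overestimate).
#'
#' @param dataset A `phantom_dataset` with noise added.
#' @param factors Positive multipliers.
#' @return Numeric vector `effective_sigma2(dataset) * factors`.
#' @export
sigma_prior_sweep <- function(dataset, factors) {
  stopifnot(is.numeric(factors), all(factors > 0))
  effective_sigma2(dataset) * factors
}

#' One-call phantom generation
#'
#' Convenience wrapper building the noise-free phantom, adding noise at the
#' requested SNR (S(b=0) = 1, so `sigma = 1/snr`) and, optionally, applying
#' the correlation-inducing processing to both clean and noisy data.
#'
#' @param size Phantom edge length (multiple of 3).
#' @param snr Signal-to-noise ratio of the b = 0 signal.
#' @param noise `"gaussian"` or `"rician"`.
#' @param correlate `"none"`, `"zerofill"` or `"smooth"`.
#' @param n_zero_cols Columns to zero for `correlate = "zerofill"`.
#' @param fwhm Kernel FWHM for `correlate = "smooth"`.
#' @param seed Integer seed for the noise.
#' @param ... Passed to [build_phantom()].
#' @return A fully populated `phantom_dataset`; `$processed_noisy` (or
#'   `$noisy` when `correlate = "none"`) is the denoiser input, and
#'   `$processed_clean` (or `$clean`) the matching ground truth.
#' @export
make_phantom_dataset <- function(size = 12L, snr = 30, noise = "gaussian",
                                 correlate = c("none", "zerofill", "smooth"),
                                 n_zero_cols = if (size == 66L) 16L else 3L,
                                 fwhm = 2, seed = NULL, ...) {
  correlate <- match.arg(correlate)
  ds <- build_phantom(size = size, ...)
  ds <- add_noise(ds, sigma = 1 / snr, model = noise, seed = seed)
  if (correlate == "zerofill") ds <- zerofill_correlate(ds, n_zero_cols)
  if (correlate == "smooth") ds <- smooth_correlate(ds, fwhm)
  ds
}

#' Window matrix of a phantom dataset
#'
#' Reshapes one field of the dataset to the voxels-by-measurements matrix
#' used for single-window denoising (all voxels in one window).
#'
#' @param dataset A `phantom_dataset`.
#' @param field Which signals to extract: `"input"` picks the denoiser
#'   input (`processed_noisy` if present, else `noisy`), `"truth"` the
#'   matching ground truth; or name a field directly.
#' @return M x N matrix (M = voxels, N = measurements).
#' @export
phantom_matrix <- function(dataset, field = c("input", "truth", "clean", "noisy",
                                              "processed_clean", "processed_noisy")) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  field <- match.arg(field)
  arr <- switch(field,
                input = dataset$processed_noisy %||% dataset$noisy,
                truth = dataset$processed_clean %||% dataset$clean,
                dataset[[field]])
  if (is.null(arr)) stop("field '", field, "' is not populated")
  matrix(arr, ncol = dim(arr)[3])
}
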