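#' Read a diffusion-weighted dataset
#'
#' Loads a NIfTI-1 volume together with FSL-style bval/bvec text files and
#' checks their consistency (the number of b-values and gradient vectors
#' must match the 4th data dimension).  Gradient vectors are normalised to
#' unit length (zero vectors, conventionally used for b = 0, are kept).
#' Volumes are used as stored: no reorientation or resampling is performed.
#'
#' @param nifti Path to a `.nii` or `.nii.gz` file.
#' @param bval,bvec Paths to whitespace-separated b-value / b-vector files
#'   (bvec as 3 rows x N columns or N x 3).
#' @return An object of class `dwi_dataset`: list with `data` (4D array),
#'   `bvals`, `bvecs` (N x 3), `affine` (4 x 4), and `header` (the RNifti
#'   image for use as a writing template).
#' @export
read_dwi <- function(nifti, bval, bvec) {
  for (f in c(nifti, bval, bvec))
    if (!file.exists(f)) stop("file not found: ", f)
  img <- RNifti::readNifti(nifti)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))  # plain array, no image metadata
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("expected a 3D or 4D NIfTI volume, got ", length(dim(data)), "D")
  bvals <- scan(bval, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (ncol(bv) != 3L)
    stop("bvec file must contain 3 x N or N x 3 numbers")
  N <- dim(data)[4]
  if (length(bvals) != N || nrow(bv) != N)
    stop("bval/bvec length (", length(bvals), "/", nrow(bv),
         ") does not match volume count (", N, ")")
  nrm <- sqrt(rowSums(bv^2))
  nz <- nrm > 0
  bv[nz, ] <- bv[nz, , drop = FALSE] / nrm[nz]
  dimnames(bv) <- NULL
  structure(list(data = data, bvals = bvals, bvecs = bv,
                 affine = structure(RNifti::xform(img), class = NULL),
                 header = img),
            class = "dwi_dataset")
}

#' Write denoising outputs
#'
#' Writes the denoised volume, component map, effective-prior map, and
#' residuals as NIfTI files carrying the reference image's spatial
#' metadata, plus a JSON sidecar with run metadata.
#'
#' @param result A [denoise_volume()] result.
#' @param prefix Output path prefix; files are written as
#'   `<prefix>_denoised.nii.gz`, `_ncomp.nii.gz`, `_sigma2.nii.gz`,
#'   `_residuals.nii.gz` and `<prefix>.json`.
#' @param reference An RNifti image (e.g. `dwi$header` from [read_dwi()])
#'   supplying the affine/header; `NULL` writes with default metadata.
#' @param extra Named list merged into the JSON sidecar (e.g. seed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_outputs <- function(result, prefix, reference = NULL, extra = list()) {
  stopifnot(inherits(result, "denoise_result"))
  wr <- function(arr, path) {
    img <- if (is.null(reference)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = reference)
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(
    denoised  = wr(result$denoised,  paste0(prefix, "_denoised.nii.gz")),
    ncomp     = wr(result$ncomp_map, paste0(prefix, "_ncomp.nii.gz")),
    residuals = wr(result$residuals, paste0(prefix, "_residuals.nii.gz")))
  if (!all(is.na(result$sigma2_map_used)))
    paths <- c(paths, sigma2 = wr(result$sigma2_map_used,
                                  paste0(prefix, "_sigma2.nii.gz")))
  meta <- c(list(method = result$method,
                 window = result$window,
                 n_failed_windows = result$n_failed_windows,
                 package_version = as.character(utils::packageVersion("pcadenoise"))),
            extra)
  json <- paste0(prefix, ".json")
  jsonlite::write_json(meta, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, sidecar = json))
}

#' Write a protocol as FSL bval/bvec files
#'
#' @param protocol A [make_protocol()] object.
#' @param bval,bvec Output paths.
#' @return Invisibly, the two paths.
#' @export
write_protocol <- function(protocol, bval, bvec) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  writeLines(paste(format(protocol$bvals, trim = TRUE), collapse = " "), bval)
  write.table(t(protocol$bvecs), bvec, row.names = FALSE, col.names = FALSE)
  invisible(c(bval = bval, bvec = bvec))
}

#' Parse a window-size string
#'
#' Converts `"11x11"` / `"9x9x3"` style specifications to an integer
#' vector, requiring positive odd dimensions (so windows have a centre
#' voxel).
#'
#' @param spec Character scalar, `"AxB"` or `"AxBxC"`.
#' @return Integer vector of length 2 or 3.
#' @export
parse_window <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(tolower(spec), "x", fixed = TRUE)[[1L]]
  if (!length(parts) %in% 2:3)
    stop("window spec must be 'AxB' or 'AxBxC', got '", spec, "'")
  dims <- suppressWarnings(as.integer(parts))
  if (any(is.na(dims)) || any(dims < 1L))
    stop("window dimensions must be positive integers, got '", spec, "'")
  if (any(dims %% 2L == 0L))
    stop("window dimensions must be odd (so the window has a centre), got '",
         spec, "'")
  dims
}
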