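#' Marchenko-Pastur distribution parameters
#'
#' Bundles the two parameters of the Marchenko-Pastur (MP) limiting
#' eigenvalue distribution of a pure-noise sample covariance matrix: the
#' noise variance `sigma2` (in squared signal units) and the matrix aspect
#' ratio `gamma = N/M` with `M >= N`, so that `0 < gamma <= 1`.
#'
#' @param sigma2 Noise variance, non-negative scalar.
#' @param gamma Aspect ratio N/M, scalar in (0, 1].
#' @return An object of class `mp_params` with elements `sigma2` and `gamma`.
#' @seealso [mp_bounds()], [mp_pdf()]
#' @examples
#' p <- mp_params(sigma2 = 1, gamma = 0.25)
#' mp_bounds(p)
#' @export
mp_params <- function(sigma2, gamma) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (sigma2 < 0)
    stop("'sigma2' must be non-negative, got ", sigma2)
  if (gamma <= 0 || gamma > 1)
    stop("'gamma' must lie in (0, 1], got ", gamma)
  structure(list(sigma2 = sigma2, gamma = gamma), class = "mp_params")
}

#' Support bounds of the Marchenko-Pastur distribution
#'
#' The MP density is supported on \eqn{[\lambda_-, \lambda_+]} with
#' \eqn{\lambda_\pm = \sigma^2 (1 \pm \sqrt{\gamma})^2}.  The width of the
#' support is therefore \eqn{\lambda_+ - \lambda_- = 4\sqrt{\gamma}\,\sigma^2},
#' which is the relation inverted by [sigma2_from_width()].
#'
#' @param params An [mp_params()] object.
#' @return A list with elements `lambda_minus` and `lambda_plus`.
#' @export
mp_bounds <- function(params) {
  stopifnot(inherits(params, "mp_params"))
  sg <- sqrt(params$gamma)
  list(lambda_minus = params$sigma2 * (1 - sg)^2,
       lambda_plus  = params$sigma2 * (1 + sg)^2)
}

#' Marchenko-Pastur probability density
#'
#' Density \eqn{p(\lambda) = \sqrt{(\lambda_+-\lambda)(\lambda-\lambda_-)} /
#' (2\pi\gamma\lambda\sigma^2)} inside the support, zero outside.
#'
#' @param lam Eigenvalue(s), non-negative numeric vector.
#' @param params An [mp_params()] object with `sigma2 > 0`.
#' @return Density values, same length as `lam`.
#' @export
mp_pdf <- function(lam, params) {
  stopifnot(inherits(params, "mp_params"), is.numeric(lam))
  if (any(lam < 0, na.rm = TRUE))
    stop("eigenvalues must be non-negative")
  b <- mp_bounds(params)
  out <- numeric(length(lam))
  inside <- lam > b$lambda_minus & lam < b$lambda_plus
  if (any(inside)) {
    l <- lam[inside]
    out[inside] <- sqrt((b$lambda_plus - l) * (l - b$lambda_minus)) /
      (2 * pi * params$gamma * l * params$sigma2)
  }
  out
}

#' Noise variance from the eigenvalue bandwidth
#'
#' Inverts the MP width relation: given the spread of the `C` smallest
#' eigenvalues assumed to carry mostly noise, estimates the noise variance as
#' \eqn{\hat\sigma^2_{MP} = (\lambda_{max} - \lambda_{min}) / (4\sqrt{\gamma_C})}
#' with \eqn{\gamma_C = C/M}.  This is the internal variance estimate of the
#' MPPCA moment-matching classifier ([classify_mppca()]).
#'
#' @param lambda_max Largest eigenvalue of the candidate noise set.
#' @param lambda_min Smallest eigenvalue of the candidate noise set.
#' @param gamma_c Ratio C/M of the candidate noise-set size to the number of
#'   window voxels; must be positive.
#' @return The bandwidth-derived variance estimate (scalar).
#' @export
sigma2_from_width <- function(lambda_max, lambda_min, gamma_c) {
  stopifnot(is.numeric(lambda_max), is.numeric(lambda_min),
            is.numeric(gamma_c), length(gamma_c) == 1L)
  if (gamma_c <= 0)
    stop("'gamma_c' must be positive, got ", gamma_c)
  if (any(lambda_min < 0) || any(lambda_max < lambda_min))
    stop("require lambda_max >= lambda_min >= 0")
  (lambda_max - lambda_min) / (4 * sqrt(gamma_c))
}
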