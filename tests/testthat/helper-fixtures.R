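# shared fixtures and small oracles, built in code at test time

modal_value <- function(x) as.numeric(names(which.max(table(x))))

# rejection-sample n eigenvalues from the MP law (independent oracle draws)
draw_mp_sample <- function(n, sigma2, gamma, seed) {
  set.seed(seed)
  p <- mp_params(sigma2, gamma)
  b <- mp_bounds(p)
  peak <- max(mp_pdf(seq(b$lambda_minus + 1e-9, b$lambda_plus - 1e-9,
                         length.out = 512), p))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(4 * n, b$lambda_minus, b$lambda_plus)
    keep <- stats::runif(4 * n) < mp_pdf(x, p) / (1.05 * peak)
    out <- c(out, x[keep])
  }
  sort(out[seq_len(n)])
}

# wrap a bare eigenvalue vector as an eigen_spectrum (for classifier tests
# that do not need eigenvectors)
fake_spectrum <- function(values, M) {
  values <- sort(values)
  N <- length(values)
  structure(list(values = values, vectors = diag(N), M = M, N = N,
                 gamma = N / M),
            class = "eigen_spectrum")
}

# single-window classification counts on a phantom dataset
phantom_counts <- function(seed, correlate = "none", prior = NULL) {
  d <- make_phantom_dataset(seed = seed, correlate = correlate)
  spec <- eigendecompose(demean_columns(phantom_matrix(d))$Xc)
  if (is.null(prior)) prior <- effective_sigma2(d)
  c(mppca = classify_mppca(spec)$n_noise,
    gpca = classify_gpca(spec, prior)$n_noise,
    tpca = classify_tpca(spec, prior)$n_noise)
}
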