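test_that("column demeaning removes means and keeps them for restoration", {
  X <- matrix(5, 4, 3)
  dm <- demean_columns(X)
  expect_equal(dm$Xc, matrix(0, 4, 3))
  expect_equal(dm$means, rep(5, 3))

  dm <- demean_columns(matrix(c(1, 3), ncol = 1))
  expect_equal(as.vector(dm$Xc), c(-1, 1))
  expect_equal(dm$means, 2)

  set.seed(3)
  dm <- demean_columns(matrix(stats::rnorm(15), 5, 3))
  expect_lt(max(abs(colSums(dm$Xc))), 1e-12)

  expect_error(demean_columns(matrix(1, 1, 3)), "at least 2 rows")
})

test_that("eigendecomposition satisfies the spectrum invariants", {
  expect_equal(eigendecompose(matrix(0, 5, 3))$values, rep(0, 3))

  # rank-1 matrix: one nonzero eigenvalue equal to ||X||_F^2 / M
  u <- c(1, -2, 3, 0.5)
  v <- c(2, -1, 4)
  Xc <- outer(u, v)
  Xc <- sweep(Xc, 2, colMeans(Xc))
  spec <- eigendecompose(Xc)
  expect_equal(sum(spec$values > 1e-12), 1)
  expect_equal(max(spec$values), sum(Xc^2) / nrow(Xc))

  set.seed(4)
  X <- matrix(stats::rnorm(40 * 12), 40, 12)
  dm <- demean_columns(X)
  spec <- eigendecompose(dm$Xc)
  # ascending order, orthonormal eigenvectors, energy conservation
  expect_true(all(diff(spec$values) >= 0))
  expect_lt(max(abs(crossprod(spec$vectors) - diag(12))), 1e-10)
  expect_equal(sum(spec$values), sum(dm$Xc^2) / 40, tolerance = 1e-10)
  expect_equal(spec$gamma, 12 / 40)

  expect_error(eigendecompose(matrix(stats::rnorm(12), 3, 4)), "M >= N")
  expect_error(eigendecompose(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("MPPCA moment matching reproduces hand-computed classifications", {
  # lambda = [1,1,1,100], M = 16: at C=4 mean 25.75 < 49.5 fails, C=3 holds
  spec <- fake_spectrum(c(1, 1, 1, 100), M = 16)
  cls <- classify_mppca(spec)
  expect_equal(cls$n_noise, 3)
  expect_equal(cls$lambda_bar_c, 1)
  expect_equal(cls$n_signal, 1)

  # equal eigenvalues: zero bandwidth, criterion holds at C = N
  cls <- classify_mppca(fake_spectrum(rep(2, 6), M = 20))
  expect_equal(cls$n_noise, 6)

  expect_equal(classify_mppca(fake_spectrum(rep(0, 4), M = 9))$n_noise, 4)
})

test_that("GPCA picks the largest small-eigenvalue set whose mean is under the prior", {
  spec <- fake_spectrum(c(0.5, 1.0, 1.5, 10), M = 16)
  expect_equal(classify_gpca(spec, 1.05)$n_noise, 3)
  expect_equal(classify_gpca(spec, 0)$n_noise, 0)
  expect_equal(classify_gpca(spec, mean(spec$values))$n_noise, 4)
  expect_error(classify_gpca(spec, -1), "non-negative")
})

test_that("TPCA thresholds eigenvalues at the prior-scaled MP upper bound", {
  spec <- fake_spectrum(c(0.5, 1.0, 1.5, 10), M = 16)
  cls <- classify_tpca(spec, 1.05)
  expect_equal(cls$threshold, (1 + sqrt(4 / 16))^2 * 1.05)  # 2.3625
  expect_equal(cls$n_noise, 3)
  expect_equal(classify_tpca(spec, 0)$n_noise, 0)
  # strict comparison: an eigenvalue exactly at the threshold is signal
  spec2 <- fake_spectrum(c(0.5, 2.25), M = 8)  # lambda_t = (1 + sqrt(1/4))^2 = 2.25
  expect_equal(classify_tpca(spec2, 1)$n_noise, 1)
})

test_that("legacy fixed-threshold classification counts eigenvalues under tau", {
  spec <- fake_spectrum(c(0.5, 1.0, 1.5, 10), M = 16)
  cls <- classify_legacy(spec, sigma2 = 1, upsilon = 1.5)
  expect_equal(cls$threshold, 2.25)
  expect_equal(cls$n_noise, 3)
  expect_equal(classify_legacy(spec, 100, 1)$n_noise, 4)
  expect_equal(classify_legacy(fake_spectrum(c(1, 5), 8), 2, 1)$n_noise, 1)
  expect_error(classify_legacy(spec, 1, 0), "positive")
})

test_that("small-spectrum classifications match brute-force oracles", {
  set.seed(5)
  for (rep in 1:40) {
    N <- sample(2:12, 1)
    lam <- sort(sample(seq(0, 3, by = 0.25), N, replace = TRUE))
    M <- N + sample(0:20, 1)
    spec <- fake_spectrum(lam, M)
    prior <- sample(seq(0, 3, by = 0.25), 1)

    # GPCA oracle: exhaustive search over all candidate set sizes
    ok <- vapply(0:N, function(c)
      c == 0 || mean(lam[seq_len(c)]) <= prior, logical(1))
    expect_identical(classify_gpca(spec, prior)$n_noise, max(which(ok)) - 1L)

    # TPCA oracle: direct strict threshold count
    lt <- (1 + sqrt(N / M))^2 * prior
    expect_identical(classify_tpca(spec, prior)$n_noise, sum(lam < lt))
  }
})

test_that("classification is equivariant under rescaling of the data", {
  set.seed(6)
  X <- matrix(stats::rnorm(60 * 15), 60, 15)
  X[, 15] <- X[, 15] * 6  # one strong component
  spec1 <- eigendecompose(demean_columns(X)$Xc)
  a <- 3.7
  spec2 <- eigendecompose(demean_columns(a * X)$Xc)
  expect_equal(spec2$values, a^2 * spec1$values, tolerance = 1e-10)
  expect_identical(classify_mppca(spec1)$n_noise, classify_mppca(spec2)$n_noise)
  expect_identical(classify_gpca(spec1, 1)$n_noise,
                   classify_gpca(spec2, a^2)$n_noise)
  expect_identical(classify_tpca(spec1, 1)$n_noise,
                   classify_tpca(spec2, a^2)$n_noise)
})

test_that("GPCA and TPCA counts are non-decreasing in the prior", {
  set.seed(7)
  X <- matrix(stats::rnorm(80 * 20), 80, 20) +
    outer(stats::rnorm(80, sd = 2), stats::rnorm(20))
  spec <- eigendecompose(demean_columns(X)$Xc)
  priors <- seq(0, 3, length.out = 50)
  cg <- vapply(priors, function(p) classify_gpca(spec, p)$n_noise, integer(1))
  ct <- vapply(priors, function(p) classify_tpca(spec, p)$n_noise, integer(1))
  expect_true(all(diff(cg) >= 0))
  expect_true(all(diff(ct) >= 0))
})

test_that("reconstruction projects onto the retained subspace correctly", {
  set.seed(8)
  X <- matrix(stats::rnorm(30 * 8), 30, 8)
  dm <- demean_columns(X)
  spec <- eigendecompose(dm$Xc)

  # C = 0: identity; C = N: column-mean matrix
  expect_equal(reconstruct(dm$Xc, spec, 0, dm$means), X)
  expect_equal(reconstruct(dm$Xc, spec, 8, dm$means),
               matrix(dm$means, 30, 8, byrow = TRUE))

  # projecting a low-rank matrix onto its own signal subspace is lossless
  L <- matrix(stats::rnorm(30 * 3), 30, 3) %*% matrix(stats::rnorm(3 * 8), 3, 8)
  dmL <- demean_columns(L)
  specL <- eigendecompose(dmL$Xc)
  expect_equal(reconstruct(dmL$Xc, specL, 8 - 3, dmL$means), L,
               tolerance = 1e-8)

  expect_error(reconstruct(dm$Xc, spec, 9, dm$means), "C")
})

test_that("nominal SNR gain follows N/(N-C)", {
  expect_equal(snr_gain(10, 0), 1)
  expect_equal(snr_gain(110, 102), 13.75)
  expect_equal(snr_gain(110, 100), 11)
  expect_error(snr_gain(10, 10), "undefined")
})

test_that("MP-spectrum fitting recovers MP-distributed eigenvalues and rejects outliers", {
  lam <- draw_mp_sample(500, sigma2 = 1, gamma = 0.25, seed = 11)
  cls <- classify_mppca_slow(fake_spectrum(lam, M = 2000))
  expect_equal(cls$n_noise, 500)
  expect_equal(cls$sigma2_mp, 1, tolerance = 0.05)

  # one huge outlier on top of an MP bulk: outlier classified as signal
  lam2 <- draw_mp_sample(200, sigma2 = 1, gamma = 0.25, seed = 12)
  lam2[200] <- 10
  cls2 <- classify_mppca_slow(fake_spectrum(lam2, M = 800))
  expect_equal(cls2$n_noise, 199)

  # degenerate equal-eigenvalue spectrum is accepted in full
  expect_equal(classify_mppca_slow(fake_spectrum(rep(1, 20), 50))$n_noise, 20)
})
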