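test_that("protocol construction yields the expected measurement counts", {
  p <- make_protocol()
  expect_equal(length(p$bvals), 110)
  expect_equal(sum(p$bvals == 0), 20)
  expect_equal(as.vector(table(p$bvals[p$bvals > 0])), c(30, 30, 30))
  nrm <- sqrt(rowSums(p$bvecs^2))
  expect_true(all(abs(nrm[p$bvals > 0] - 1) < 1e-8))
  expect_true(all(nrm[p$bvals == 0] == 0))

  expect_equal(length(make_protocol(5, list(c(2, 30)))$bvals), 35)
  expect_equal(length(make_protocol(1, list())$bvals), 1)
  # deterministic: two calls agree exactly
  expect_identical(make_protocol(), p)
})

test_that("compartment signals follow the multi-tensor closed form", {
  p <- make_protocol(2, list(c(3, 10)))
  iso <- compartment_tensor(0.7, 0.7, c(1, 0, 0))
  S <- compartment_signal(p, list(list(fraction = 1, tensor = iso)))
  expect_equal(S[p$bvals == 0], rep(1, 2))
  expect_equal(S[p$bvals == 3], rep(exp(-3 * 0.7), 10))

  # two sticks/zeppelins with the gradient perpendicular to both axes
  pz <- structure(list(bvals = 3, bvecs = matrix(c(0, 0, 1), 1)),
                  class = "dwi_protocol")
  comps <- list(
    list(fraction = 0.5, tensor = compartment_tensor(1.8, 0, c(1, 0, 0))),
    list(fraction = 0.5, tensor = compartment_tensor(1.5, 0.5, c(0, 1, 0))))
  expect_equal(compartment_signal(pz, comps), 0.5 + 0.5 * exp(-1.5))

  expect_error(compartment_signal(p, list(list(fraction = 0.7, tensor = iso))),
               "sum to 1")
  expect_error(compartment_tensor(0.5, 0.7, c(1, 0, 0)), "ad >= rd")
})

test_that("the noise-free phantom has rank exactly 8 after demeaning", {
  d <- build_phantom()
  expect_equal(dim(d$clean), c(12, 12, 110))
  expect_true(all(abs(d$clean[, , 1] - 1) < 1e-12))  # b0 normalised to 1

  spec <- eigendecompose(demean_columns(matrix(d$clean, ncol = 110))$Xc)
  expect_equal(sum(spec$values > 1e-8 * max(spec$values)), 8)

  # degeneracy: making the three top portions identical drops the rank to 6
  D <- default_fibre_directions()
  D[2, ] <- D[1, ]; D[3, ] <- D[1, ]
  frac <- d$fractions_grid
  frac[1, ] <- 0.35
  dflat <- build_phantom(fractions = frac, fibre_directions = D)
  specf <- eigendecompose(demean_columns(matrix(dflat$clean, ncol = 110))$Xc)
  expect_equal(sum(specf$values > 1e-8 * max(specf$values)), 6)

  # collinear crossing directions are rejected
  Dbad <- default_fibre_directions(); Dbad[4, ] <- Dbad[1, ]
  expect_error(build_phantom(fibre_directions = Dbad), "collinear")

  # larger variant keeps the 9-portion rank
  d66 <- build_phantom(size = 66)
  spec66 <- eigendecompose(demean_columns(matrix(d66$clean, ncol = 110))$Xc)
  expect_equal(sum(spec66$values > 1e-8 * max(spec66$values)), 8)
})

test_that("rank 8 and detectability hold across alternative direction sets", {
  rot <- function(ax, th) {
    c3 <- cos(th); s3 <- sin(th)
    switch(ax,
           x = rbind(c(1, 0, 0), c(0, c3, -s3), c(0, s3, c3)),
           y = rbind(c(c3, 0, s3), c(0, 1, 0), c(-s3, 0, c3)),
           z = rbind(c(c3, -s3, 0), c(s3, c3, 0), c(0, 0, 1)))
  }
  base <- default_fibre_directions()
  alts <- list(base %*% t(rot("z", 0.4)),
               base %*% t(rot("x", 0.7)),
               base %*% t(rot("y", 1.1)))
  for (D in alts) {
    d <- build_phantom(fibre_directions = D)
    spec <- eigendecompose(demean_columns(matrix(d$clean, ncol = 110))$Xc)
    vals <- rev(spec$values)
    expect_equal(sum(vals > 1e-8 * vals[1]), 8)
    # all 8 signal eigenvalues clear the SNR-30 noise spectrum edge
    edge <- (1 / 30)^2 * (1 + sqrt(110 / 144))^2
    expect_gt(vals[8], 2 * edge)
  }
})

test_that("noise corruption matches its models and seeds reproduce exactly", {
  d <- build_phantom()
  expect_identical(add_noise(d$clean, 0, "gaussian"), d$clean)

  set.seed(41)
  x <- add_noise(array(1, c(10, 10, 100)), sigma = 1 / 30, model = "gaussian",
                 seed = 7)
  expect_equal(stats::sd(x - 1), 1 / 30, tolerance = 0.03)
  y <- add_noise(array(1, c(10, 10, 100)), sigma = 1 / 30, model = "gaussian",
                 seed = 7)
  expect_identical(x, y)

  # Rician floor on zero signal: Rayleigh mean sigma * sqrt(pi/2)
  r <- add_noise(array(0, c(50, 50, 8)), sigma = 2, model = "rician", seed = 8)
  expect_true(all(r >= 0))
  expect_equal(mean(r), 2 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("k-space zero-filling is the identity at 0 columns and obeys Parseval", {
  set.seed(42)
  img <- array(stats::rnorm(12 * 12 * 3), c(12, 12, 3))
  expect_equal(zerofill_correlate(img, 0), img)
  z <- zerofill_correlate(img[, , 1], 3)
  expect_true(is.matrix(z))

  # zeroing 3 of 12 columns keeps exactly 9/12 of white-noise power
  noise <- array(stats::rnorm(12 * 12 * 2500), c(12, 12, 2500))
  pn <- zerofill_correlate(noise, 3)
  expect_equal(stats::var(as.vector(pn)), 9 / 12, tolerance = 0.02)

  # linearity: processing commutes with addition of clean and noise parts
  d <- make_phantom_dataset(seed = 43, correlate = "zerofill")
  expect_equal(d$processed_noisy - d$processed_clean,
               zerofill_correlate(d$noisy - d$clean, 3), tolerance = 1e-12)
  # processed ground truth of the rank-8 phantom stays exactly computable
  expect_equal(d$processed_clean, zerofill_correlate(d$clean, 3))
  expect_error(zerofill_correlate(img, 12), "cannot zero")
})

test_that("Gaussian smoothing preserves constants and induces autocorrelation", {
  img <- array(5, c(10, 10, 2))
  expect_equal(smooth_correlate(img, 0), img)
  expect_equal(smooth_correlate(img, 2), img, tolerance = 1e-12)

  set.seed(44)
  noise <- array(stats::rnorm(40 * 40 * 30), c(40, 40, 30))
  sm <- smooth_correlate(noise, 2)
  lag1 <- stats::cor(as.vector(sm[-40, , ]), as.vector(sm[-1, , ]))
  expect_gt(lag1, 0.3)
})

test_that("phantom datasets are reproducible and priors sweep monotonically", {
  d1 <- make_phantom_dataset(seed = 45, correlate = "zerofill")
  d2 <- make_phantom_dataset(seed = 45, correlate = "zerofill")
  expect_identical(d1$processed_noisy, d2$processed_noisy)

  expect_equal(effective_sigma2(d1), (1 / 30)^2 * 9 / 12)
  sw <- sigma_prior_sweep(d1, c(0.5, 1, 2, 4))
  expect_equal(sw, effective_sigma2(d1) * c(0.5, 1, 2, 4))
  expect_true(all(diff(sw) > 0))
  expect_error(sigma_prior_sweep(d1, c(-1, 2)), "factors > 0")
})
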