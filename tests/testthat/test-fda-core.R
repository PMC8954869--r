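test_that("Fourier basis has the stated closed form and exact orthonormality", {
  # K = 1: constant 1/sqrt(T)
  expect_equal(evalFourierBasis(1, c(0.1, 0.9), T = 1),
               matrix(1, 2, 1))
  # K = 3 at t = 0: (1, sin(0) = 0, sqrt(2) cos(0))
  expect_equal(drop(evalFourierBasis(3, 0)), c(1, 0, sqrt(2)))
  # numerically integrated Gram matrix ~ identity (trapezoid oracle)
  pts <- seq(0, 1, length.out = 2001)
  Phi <- evalFourierBasis(25, pts)
  G <- trapezoidGram(Phi, Phi, pts)
  expect_lt(max(abs(G - diag(25))), 1e-6)
  # domain errors
  expect_error(evalFourierBasis(0, 0.5), "K")
  expect_error(evalFourierBasis(3, c(-0.1, 0.5)), "within")
})

test_that("roughness matrix matches closed-form derivatives and quadrature", {
  b <- fourierBasis(K = 7, M = 50)
  R2 <- roughnessMatrix(b, 2L)$R2
  expect_equal(R2[1, 1], 0)                      # constant has zero curvature
  expect_equal(R2[2, 2], (2 * pi)^4)             # first sine pair
  expect_equal(R2[3, 3], (2 * pi)^4)
  expect_equal(R2[4, 4], (4 * pi)^4)
  # quadrature oracle: second derivatives integrated numerically
  pts <- seq(0, 1, length.out = 4001)
  h <- 2 * pi * (1:3)
  D2 <- cbind(0,
              -h[1]^2 * sqrt(2) * sin(h[1] * pts),
              -h[1]^2 * sqrt(2) * cos(h[1] * pts),
              -h[2]^2 * sqrt(2) * sin(h[2] * pts),
              -h[2]^2 * sqrt(2) * cos(h[2] * pts),
              -h[3]^2 * sqrt(2) * sin(h[3] * pts),
              -h[3]^2 * sqrt(2) * cos(h[3] * pts))
  Gq <- trapezoidGram(D2, D2, pts)
  expect_lt(max(abs(Gq - R2)) / max(R2), 1e-6)
  offdiag <- R2[row(R2) != col(R2)]
  expect_true(all(offdiag == 0))
  expect_error(roughnessMatrix(b, 0L), "m")
})

test_that("penalized smoothing solves the stated normal equations", {
  b <- fourierBasis(K = 5, M = 12)
  # constant genotype row lies in the span and is reproduced exactly
  sm <- smoothGenotypeRegion(matrix(2, 3, 12), b, lambda_x = 0.7)
  recon <- basisMatrix(b) %*% t(sm$d)
  expect_equal(max(abs(recon - 2)), 0, tolerance = 1e-10)
  expect_equal(sm$d[1, 1], 2, tolerance = 1e-10)   # 2 sqrt(T) on constant
  # K = M interpolation on an invertible grid
  bi <- fourierBasis(K = 8, evalPoints = seq(0.03, 0.92, length.out = 8))
  Xr <- matrix(rbinom(16, 2, 0.4), 2, 8)
  smi <- smoothGenotypeRegion(Xr, bi, 0)
  expect_equal(max(abs(basisMatrix(bi) %*% t(smi$d) - t(Xr))), 0,
               tolerance = 1e-8)
  # random instance matches the independent QR minimizer of the penalized
  # sum of squares
  set.seed(42)
  b5 <- fourierBasis(K = 5, M = 12)
  X <- matrix(rbinom(60, 2, 0.3), 5, 12)
  sm5 <- smoothGenotypeRegion(X, b5, lambda_x = 0.1)
  expect_equal(sm5$d, pensseOracle(X, b5, 0.1), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("smoother is linear and shrinkage is monotone in lambda_x", {
  set.seed(7)
  b <- fourierBasis(K = 9, M = 15)
  X1 <- matrix(rbinom(30, 2, 0.3), 2, 15)
  X2 <- matrix(rbinom(30, 2, 0.4), 2, 15)
  sA <- smoothGenotypeRegion(3 * X1 - 2 * X2, b, 0.05)$d
  sB <- 3 * smoothGenotypeRegion(X1, b, 0.05)$d -
    2 * smoothGenotypeRegion(X2, b, 0.05)$d
  expect_equal(sA, sB, tolerance = 1e-10)
  R2 <- roughnessMatrix(b)$R2
  bend <- vapply(c(0, 0.01, 0.1, 1, 10), function(l) {
    d <- smoothGenotypeRegion(X1, b, l)$d
    sum(diag(d %*% R2 %*% t(d)))
  }, numeric(1))
  expect_true(all(diff(bend) <= 1e-10))
})

test_that("cross-product of matched orthonormal bases is the identity", {
  b25 <- fourierBasis(K = 25, M = 30)
  b15 <- fourierBasis(K = 15, M = 30)
  expect_equal(crossProductMatrix(b25, b25), diag(25))
  J <- crossProductMatrix(b25, b15)
  expect_equal(J, diag(25)[, 1:15])
  bT <- fourierBasis(K = 5, evalPoints = c(0.5, 1.5), T = 2)
  expect_error(crossProductMatrix(b25, bT), "domain")
})
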