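test_that("AIC matches the n ln(Rss/n) + 2K formula", {
  expect_equal(aicValue(10, 10, 2), 4)
  expect_equal(aicValue(10 * exp(1), 10, 0), 10)
  # strictly increasing in K at fixed rss, n
  a <- vapply(0:6, function(K) aicValue(3.7, 50, K), numeric(1))
  expect_true(all(diff(a) == 2))
  expect_warning(expect_identical(aicValue(0, 10, 1), -Inf), "perfect")
})

test_that("design blocks compose weighting and smoothing as specified", {
  st <- toyStudy(seed = 2, n = 40, M = 10)
  blocks <- regionDesignBlocks(st$dataset, K = 5)
  expect_length(blocks, 25)
  expect_true(all(vapply(blocks, function(b) all(dim(b) == c(40, 5)),
                         logical(1))))
  # explicit composition: smoothing of the raw genotypes
  b <- fourierBasis(K = 5, M = 10)
  expect_equal(blocks[[3]],
               smoothGenotypeRegion(genotypes(st$dataset, 3), b, 0)$d)
  # uniform Beta(1,1) weights change nothing
  expect_equal(regionDesignBlocks(st$dataset, K = 5,
                                  weights = locusWeightScheme(1, 1)),
               blocks)
})

test_that("backward selection keeps true signal and discards noise blocks", {
  kept <- 0L; noiseKept <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    blocks <- lapply(1:6, function(p) matrix(rnorm(n * 4), n, 4))
    names(blocks) <- paste0("g", 1:6)
    y <- blocks[[2]] %*% c(2, -1.5, 1, 0.5) + rnorm(n, 0, 1)
    m <- backwardStepwise(drop(y), blocks)
    if (2L %in% m$active) kept <- kept + 1L
    noiseKept <- noiseKept + length(setdiff(m$active, 2L))
    # final AIC never exceeds the full-model AIC
    rssFull <- sum(lm.fit(cbind(1, do.call(cbind, blocks)),
                          drop(y))$residuals^2)
    expect_lte(m$aic, aicValue(rssFull, n, 24) + 1e-8)
  }
  expect_equal(kept, 10L)
  expect_lt(noiseKept / 50, 0.2)    # each noise block costs 2K = 8 AIC
  # pure-noise outcome: near-empty models
  emptyish <- vapply(1:10, function(s) {
    set.seed(100 + s)
    blocks <- lapply(1:6, function(p) matrix(rnorm(500 * 4), 500, 4))
    names(blocks) <- paste0("g", 1:6)
    length(backwardStepwise(rnorm(500), blocks)$active)
  }, numeric(1))
  expect_lt(mean(emptyish), 1)
})

test_that("P = 1 stopping rule leaves a useful block in place", {
  set.seed(9)
  b1 <- matrix(rnorm(200 * 3), 200, 3)
  y <- drop(b1 %*% c(1, 1, -1)) + rnorm(200, 0, 0.5)
  m <- backwardStepwise(y, list(g1 = b1))
  expect_equal(m$active, 1L)
})

test_that("partial F test matches the nested-RSS formula and edge cases", {
  set.seed(21)
  n <- 120
  blocks <- list(g1 = matrix(rnorm(n * 3), n, 3),
                 g2 = matrix(rnorm(n * 3), n, 3))
  y <- drop(blocks$g1 %*% c(1, 1, 1)) + rnorm(n)
  m <- backwardStepwise(y, blocks)
  if (all(1:2 %in% m$active)) {
    r <- partialFTest(m, 1)
    # independent oracle: anova() on the two nested lm fits
    f_full <- lm(y ~ blocks$g1 + blocks$g2)
    f_red <- lm(y ~ blocks$g2)
    ora <- anova(f_red, f_full)
    expect_equal(r$F, ora$F[2], tolerance = 1e-10)
    expect_equal(r$p_value, ora$`Pr(>F)`[2], tolerance = 1e-10)
  }
  # duplicated block: the reduced model loses nothing, F collapses to ~0
  dup <- list(g1 = blocks$g1, g2 = blocks$g1, g3 = blocks$g2)
  suppressWarnings(mdup <- backwardStepwise(y, dup))
  if (1L %in% mdup$active && 2L %in% mdup$active) {
    expect_lt(partialFTest(mdup, 1)$F, 1e-6)
  }
  expect_error(partialFTest(m, 3), "not in")
})

test_that("null p-values from the partial F are uniform over replicates", {
  # tested block independent of y: p ~ Uniform(0, 1)
  set.seed(31)
  pvals <- vapply(1:200, function(i) {
    n <- 150
    blocks <- list(g1 = matrix(rnorm(n * 2), n, 2),
                   g2 = matrix(rnorm(n * 2), n, 2))
    y <- drop(blocks$g1 %*% c(1.5, -1)) + rnorm(n, 0, 0.5)
    br <- fregion:::blockRegression(y, blocks)
    m <- structure(list(active = 1:2, rss = fregion:::rssForBlocks(br, 1:2),
                        K = 4L, n = n, br = br), class = "StepModel")
    partialFTest(m, 2)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("step test output contract holds and ordering beats noise", {
  st <- toyStudy(seed = 6, n = 400, M = 12, assoc = c(3L, 17L))
  res <- stepTest(st$dataset, K = 7)
  expect_equal(nrow(res), 25L)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$p_value[!res$selected] == 1))
  # associated regions get smaller p-values than unassociated ones
  expect_lt(mean(res$p_value[st$assoc]), mean(res$p_value[-st$assoc]))
  # uniform weights reproduce the unweighted test exactly
  resw <- stepTest(st$dataset, K = 7, weights = locusWeightScheme(1, 1))
  expect_equal(res, resw)
})

test_that("results are invariant to joint permutation of individuals", {
  st <- toyStudy(seed = 8, n = 150, M = 10, assoc = c(2L, 9L))
  res <- stepTest(st$dataset, K = 5)
  set.seed(1); perm <- sample(150)
  regs <- lapply(st$dataset@regions, function(r)
    markerRegion(r@regionId, r@X[perm, ], r@positions, r@maf))
  dperm <- multiRegionDataset(regs, trait(st$dataset)[perm])
  expect_equal(stepTest(dperm, K = 5), res, tolerance = 1e-8)
})

test_that("forward selection is available and behaves sanely", {
  st <- toyStudy(seed = 12, n = 300, M = 10, assoc = c(5L, 20L))
  resf <- stepTest(st$dataset, K = 5, direction = "forward")
  expect_true(all(resf$p_value[st$assoc] < 0.05))
})
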