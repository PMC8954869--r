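test_that("SCAD penalty has the standard closed form and smooth knots", {
  expect_equal(scadPenalty(0, 1), 0)
  expect_equal(scadPenalty(0.5, 1), 0.5)                 # linear zone
  expect_equal(scadPenalty(5, 1, 3.7), (3.7 + 1) / 2)    # saturated: 2.35
  expect_equal(scadPenalty(10, 1, 3.7), 2.35)
  # continuity and derivative continuity at u = lam and u = a lam
  for (lam in c(0.5, 1, 2)) {
    a <- 3.7; eps <- 1e-7
    for (knot in c(lam, a * lam)) {
      expect_equal(scadPenalty(knot - eps, lam, a),
                   scadPenalty(knot + eps, lam, a), tolerance = 1e-6)
      dl <- (scadPenalty(knot, lam, a) - scadPenalty(knot - eps, lam, a)) / eps
      dr <- (scadPenalty(knot + eps, lam, a) - scadPenalty(knot, lam, a)) / eps
      expect_equal(dl, dr, tolerance = 1e-5)
      expect_equal(scadDerivative(knot - eps, lam, a),
                   scadDerivative(knot + eps, lam, a), tolerance = 1e-5)
    }
  }
  expect_error(scadPenalty(1, 1, a = 2), "exceed 2")
})

test_that("lambda = gamma = 0 reduces to unpenalized functional least squares", {
  st <- toyStudy(seed = 4, n = 120, M = 10, assoc = c(1L, 2L))
  ds <- multiRegionDataset(st$dataset@regions[1:4], trait(st$dataset))
  fit <- fitMultiSLoS(ds, K = 7, config = slosConfig(0, 0))
  prob <- attr(fit, "problem")
  # oracle: direct projection RSS of y on the centered design
  U <- prob$Uc
  ols <- lm.fit(cbind(1, U), prob$yc + prob$ybar)
  expect_equal(fit@rss, sum(ols$residuals^2), tolerance = 1e-6)
  expect_false(any(nullRegions(fit)))
})

test_that("LQA loss path is monotone and the fit reproducible", {
  st <- toyStudy(seed = 14, n = 300, M = 12, assoc = c(2L, 7L))
  ds <- multiRegionDataset(st$dataset@regions[1:10], trait(st$dataset))
  fit <- fitMultiSLoS(ds, K = 9, config = slosConfig(0.05, 0.05))
  lp <- attr(fit, "solution")$lossPath
  expect_true(all(diff(lp) <= 1e-6 * pmax(abs(lp[-length(lp)]), 1)))
  fit2 <- fitMultiSLoS(ds, K = 9, config = slosConfig(0.05, 0.05))
  expect_equal(fit@coef, fit2@coef)
})

test_that("pure-noise regions are compressed to null in most replicates", {
  nulled <- vapply(1:10, function(s) {
    st <- toyStudy(seed = 400 + s, n = 500, M = 10, assoc = c(1L, 2L))
    ds <- multiRegionDataset(st$dataset@regions[1:6], nullTrait(500))
    fit <- fitMultiSLoS(ds, K = 7, config = slosConfig(0.05, 0.05))
    mean(nullRegions(fit))
  }, numeric(1))
  expect_gt(mean(nulled), 0.8)
})

test_that("increasing lambda never decreases compression on a fixed dataset", {
  st <- toyStudy(seed = 15, n = 200, M = 10, assoc = c(1L, 3L))
  ds <- multiRegionDataset(st$dataset@regions[1:5], trait(st$dataset))
  nullCounts <- vapply(c(0.005, 0.02, 0.08, 0.3), function(l) {
    fit <- fitMultiSLoS(ds, K = 7, config = slosConfig(0.02, l))
    sum(vapply(fit@nullCoefMask, sum, integer(1)))
  }, integer(1))
  expect_true(all(diff(nullCounts) >= 0))
})

test_that("locally sparse recovery finds the null outer thirds", {
  # single region, beta nonzero only on the middle third of the markers
  jacc <- vapply(1:5, function(s) {
    set.seed(600 + s)
    n <- 500; M <- 30
    X <- sampleDiploids(makeCommonPool(M, 4000), n)
    betas <- numeric(M); mid <- 11:20
    betas[mid] <- 0.25
    y <- drop(X %*% betas) + rnorm(n, 0, 0.1)
    ds <- multiRegionDataset(list(markerRegion("g1", X)), y)
    fit <- fitMultiSLoS(ds, K = 25, config = slosConfig(0.05, 0.05))
    est <- which(fit@nullCoefMask[[1]])
    Kb <- length(fit@coef[[1]])
    # coefficient k sits near marker k - 1 on the padded B-spline ladder
    truthNull <- setdiff(seq_len(Kb), 11:22)
    length(intersect(est, truthNull)) / length(union(est, truthNull))
  }, numeric(1))
  expect_gt(mean(jacc), 0.5)
})

test_that("non-null coefficient counts drive the adjusted degrees of freedom", {
  st <- toyStudy(seed = 44, n = 400, M = 12, assoc = c(1L, 4L))
  ds <- multiRegionDataset(st$dataset@regions[1:6], trait(st$dataset))
  fit <- fitMultiSLoS(ds, K = 9, config = slosConfig(0.02, 0.02))
  counts <- vapply(1:6, function(p) countNonnullCoefficients(fit, p),
                   integer(1))
  expect_equal(counts == 0, unname(nullRegions(fit)))
  B <- which(!nullRegions(fit))
  for (b in B) {
    r <- adjustedPartialF(fit, b)
    expect_equal(r$df1, counts[b])
    # bookkeeping: df_red + other non-null counts + 1 + df_full = n
    expect_equal(r$df1 + sum(counts[setdiff(B, b)]) + 1 + r$df2, 400)
  }
  # fully null regions are excluded with p = 1
  if (any(nullRegions(fit))) {
    r0 <- adjustedPartialF(fit, which(nullRegions(fit))[1])
    expect_false(r0$selected)
    expect_equal(r0$p_value, 1)
  }
})

test_that("without compression the adjusted F equals the plain partial F", {
  # lam = 0: no coefficients are nulled, so the adjustment is vacuous and the
  # OLS-refit F statistic must match a direct nested linear model comparison
  st <- toyStudy(seed = 70, n = 300, M = 8, assoc = c(1L, 2L))
  ds <- multiRegionDataset(st$dataset@regions[1:3], trait(st$dataset))
  fit <- fitMultiSLoS(ds, K = 5, config = slosConfig(0, 0))
  prob <- attr(fit, "problem")
  r <- adjustedPartialF(fit, 2)
  y <- trait(ds)
  Ufull <- prob$Uc
  ii <- prob$colIdx[[2]]
  f_full <- lm.fit(cbind(1, Ufull), y)
  f_red <- lm.fit(cbind(1, Ufull[, -ii, drop = FALSE]), y)
  q <- length(ii)
  df2 <- 300 - ncol(Ufull) - 1
  Fora <- ((sum(f_red$residuals^2) - sum(f_full$residuals^2)) / q) /
    (sum(f_full$residuals^2) / df2)
  expect_equal(r$F, Fora, tolerance = 1e-6)
  expect_equal(r$df1, q)
  expect_equal(r$df2, df2)
})

test_that("region-type weighted configurations populate per-region parameters", {
  cfg <- wslosConfig(c(1, 3), c(2, 4))
  expect_equal(cfg@gamma, c(0.02, 0.01, 0.02, 0.01))
  expect_equal(cfg@lam, c(0.05, 0.0025, 0.05, 0.0025))
  expect_error(wslosConfig(c(1, 2), c(2, 3)), "disjoint")
  # homogeneous multi-SLoS defaults for an all-common study
  expect_equal(defaultSLoSConfig("common25")@gamma, 0.1)
  expect_equal(defaultSLoSConfig("rare25")@lam, 0.01)
  expect_equal(defaultSLoSConfig("hybridI")@gamma, 0.05)
  expect_equal(defaultSLoSConfig("mixed10")@lam, 0.001)
  # empty rare set degenerates to a homogeneous config
  cfg0 <- wslosConfig(1:3, integer(0))
  expect_equal(unique(cfg0@gamma), 0.02)
})

test_that("slosTest separates associated from null regions", {
  st <- toyStudy(seed = 77, n = 600, M = 15, assoc = c(2L, 5L))
  ds <- multiRegionDataset(st$dataset@regions[1:8], trait(st$dataset))
  res <- slosTest(ds, K = 11, config = slosConfig(0.05, 0.05))
  expect_equal(nrow(res), 8L)
  expect_true(all(res$p_value[c(2, 5)] < 0.05))
  expect_true(all(res$p_value[!res$selected] == 1))
})
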