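test_that("common pools hit their target frequencies within binomial bounds", {
  p <- makeCommonPool(20, H = 4000, mafLow = 0.299, mafHigh = 0.301, seed = 1)
  realized <- colMeans(p@haps)
  expect_true(all(abs(realized - 0.3) < 3 * sqrt(0.3 * 0.7 / 4000) + 0.001))
  # determinism
  p2 <- makeCommonPool(20, H = 4000, mafLow = 0.299, mafHigh = 0.301, seed = 1)
  expect_identical(p@haps, p2@haps)
  expect_error(makeCommonPool(5, mafLow = 0.4, mafHigh = 0.2), "mafLow")
  # normal-law variant stays inside the range
  pn <- makeCommonPool(50, H = 500, mafDist = "normal", seed = 2)
  expect_true(all(pn@targetMaf > 0.05 & pn@targetMaf < 0.5))
})

test_that("rare pools are polymorphic, rare, and sliced from a long panel", {
  panel <- makeRarePanel(120, H = 3000)
  expect_true(all(colMeans(panel@haps) > 0))
  expect_true(all(panel@targetMaf < 0.01))
  set.seed(3)
  s1 <- makeRarePool(30, H = 3000, pool = panel)
  s2 <- makeRarePool(30, H = 3000, pool = panel)
  expect_false(identical(s1@haps, s2@haps))    # different random offsets
  expect_true(all(colMeans(s1@haps) < 0.01 + 1e-9))
  expect_error(makeRarePool(200, H = 3000, pool = panel), "exceeds")
  expect_error(makeRarePool(10, mafMax = 0.2), "mafMax")
})

test_that("diploid sampling doubles pool frequencies in expectation", {
  pool <- new("HaplotypePool", haps = matrix(1L, 50, 3),
              targetMaf = rep(0.5, 3), rare = FALSE)
  G <- sampleDiploids(pool, 10, seed = 4)
  expect_true(all(G == 2))
  p <- makeCommonPool(10, H = 5000, seed = 5)
  G2 <- sampleDiploids(p, 3000, seed = 6)
  q <- colMeans(p@haps)
  se <- sqrt(2 * q * (1 - q) / 3000)
  expect_true(all(abs(colMeans(G2) - 2 * q) < 4 * se))
  expect_identical(sampleDiploids(p, 100, seed = 7),
                   sampleDiploids(p, 100, seed = 7))
  expect_error(sampleDiploids(p, 50000), "more individuals")
})

test_that("layouts assemble the stated region mixtures", {
  des <- simulationDesign("rare25", n = 100, H = 600, snpsPerRegion = 8)
  ds <- assembleMultiRegion(des, seed = 8)
  expect_equal(nRegions(ds), 25L)
  expect_true(all(unlist(lapply(ds@regions, function(r) r@maf)) < 0.05))
  desII <- simulationDesign("hybridII", n = 150, H = 800, snpsPerRegion = 20)
  dsII <- assembleMultiRegion(desII, seed = 9)
  # census by a 0.02 cut: realized diploid frequencies of rare columns sit
  # below it, common columns (drawn above 0.05) above it
  frac <- vapply(dsII@regions, function(r) mean(r@maf >= 0.02), numeric(1))
  expect_lt(abs(mean(frac) - 0.4), 0.1)      # 40% common columns per region
  desX <- simulationDesign("mixed10", n = 150, H = 800, snpsPerRegion = 40)
  dsX <- assembleMultiRegion(desX, seed = 10)
  expect_equal(nRegions(dsX), 10L)
  rare4 <- mean(regionMAF(dsX, 4) < 0.02)
  expect_true(abs(rare4 - 0.95) < 0.1)       # region 4 is 95% rare
  desH <- simulationDesign("hybridI", n = 100, H = 600, snpsPerRegion = 8)
  dsH <- assembleMultiRegion(desH, seed = 11)
  types <- substr(regionIds(dsH), 1, 4)
  expect_equal(sum(types == "comm"), 15L)
  expect_equal(sum(types == "rare"), 10L)
})

test_that("effect law matches the MAF-driven closed form and is monotone", {
  expect_equal(effectMagnitude(0.5), 0)
  expect_equal(effectMagnitude(0.005), 0.75)
  expect_equal(effectMagnitude(0.05), 0.375)
  expect_error(effectMagnitude(0), "infinite")
  grid <- seq(0.001, 0.5, length.out = 200)
  expect_true(all(diff(effectMagnitude(grid)) < 0))
})

test_that("scenario sign patterns count out as specified", {
  des <- simulationDesign("common25", n = 80, H = 500, snpsPerRegion = 10,
                          assocRegions = c(2L, 4L, 5L, 7L, 10L))
  ds <- assembleMultiRegion(des, seed = 12)
  effI <- assignEffects(des, ds, seed = 13)
  expect_equal(nrow(effI), 15L)
  expect_true(all(effI$beta > 0))
  desII <- simulationDesign("common25", n = 80, H = 500, snpsPerRegion = 10,
                            assocRegions = c(2L, 4L, 5L, 7L, 10L),
                            scenario = "II")
  effII <- assignEffects(desII, ds, seed = 14)
  expect_equal(sum(effII$beta < 0), 6L)
  expect_equal(length(unique(effII$region[effII$beta < 0])), 2L)
  desIII <- simulationDesign("common25", n = 80, H = 500, snpsPerRegion = 10,
                             assocRegions = c(2L, 4L, 5L, 7L, 10L),
                             scenario = "III")
  effIII <- assignEffects(desIII, ds, seed = 15)
  expect_equal(sum(effIII$beta < 0), 5L)
  expect_equal(as.vector(table(effIII$region[effIII$beta < 0])),
               rep(1L, 5))
  # mixed10 scenario II flips the fixed regions 4 and 7
  desM <- simulationDesign("mixed10", n = 80, H = 500, snpsPerRegion = 40,
                           scenario = "II")
  dsM <- assembleMultiRegion(desM, seed = 16)
  effM <- assignEffects(desM, dsM, seed = 17)
  expect_setequal(unique(effM$region[effM$beta < 0]), c(4L, 7L))
})

test_that("traits follow the additive model with the stated noise", {
  st <- toyStudy(seed = 20, n = 50, M = 6, assoc = c(1L, 2L))
  eff <- st$effects
  y0 <- simulateTrait(st$dataset, eff, sigmaE = 0)
  manual <- rowSums(vapply(seq_len(nrow(eff)), function(k)
    genotypes(st$dataset, eff$region[k])[, eff$locus[k]] * eff$beta[k],
    numeric(50)))
  expect_equal(y0, manual)
  # single locus, beta = 1, no noise: the genotype column itself
  one <- data.frame(region = 1L, locus = 2L, maf = 0.2, beta = 1)
  expect_equal(simulateTrait(st$dataset, one, sigmaE = 0),
               genotypes(st$dataset, 1)[, 2])
  set.seed(30)
  expect_equal(var(nullTrait(10000)), 0.01, tolerance = 0.03)
})

test_that("studies are bit-reproducible from design + seed", {
  des <- simulationDesign("common25", n = 60, H = 400, snpsPerRegion = 6)
  s1 <- simulateStudy(des, seed = 99)
  s2 <- simulateStudy(des, seed = 99)
  expect_identical(lapply(s1$dataset@regions, function(r) r@X),
                   lapply(s2$dataset@regions, function(r) r@X))
  expect_identical(trait(s1$dataset), trait(s2$dataset))
  expect_identical(s1$effects, s2$effects)
})

test_that("LD chains reach their target adjacent correlation", {
  lp <- ldHaplotypes(25, 3000, 0.25, 0.64, seed = 41)
  r2 <- vapply(1:24, function(j) cor(lp@haps[, j], lp@haps[, j + 1])^2,
               numeric(1))
  expect_gt(median(r2), 0.2)
  expect_lt(median(r2), 0.7)
  l0 <- ldHaplotypes(10, 3000, 0, 0, seed = 42)
  r20 <- vapply(1:9, function(j) cor(l0@haps[, j], l0@haps[, j + 1])^2,
                numeric(1))
  expect_lt(median(r20), 0.01)
  expect_error(ldHaplotypes(5, 100, r2Low = 0.5, r2High = 0.4), "r2Low")
})
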