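# Synthetic-data engine: haplotype pools, diploid sampling, multi-region
# layouts, MAF-driven effect sizes under three sign scenarios, and trait
# simulation. Emulates a SKAT-style simulation study: rare-variant pools with
# left-skewed frequencies below 0.01, common-variant pools with uniform
# frequencies, diploids drawn from 10,000 haplotypes.

#' Construct a simulation design
#'
#' @param layout "rare25", "common25", "hybridI", "hybridII" or "mixed10".
#' @param n individuals (default 2000).
#' @param H haplotype pool size (default 10000).
#' @param snpsPerRegion markers per region (default 60).
#' @param assocRegions associated region indices; empty means "draw 5 at
#'   random each replicate" for the 25-region layouts. The mixed10 layout
#'   defaults to the fixed set {2, 4, 5, 7, 10}.
#' @param lociPerRegion associated loci per associated region (default 3).
#' @param scenario "I" (all effects positive), "II" (all loci negative in two
#'   of the associated regions — fixed to regions 4 and 7 for mixed10,
#'   a random 2-of-5 otherwise), or "III" (one random locus negative per
#'   associated region).
#' @param sigmaE residual standard deviation of the trait model.
#' @param mafLow,mafHigh common-variant allele-frequency range.
#' @param mafDist "uniform" or "normal" common-variant frequency law.
#' @param rareMafMax rare-variant frequency ceiling.
#' @param assocMafMax eligibility ceiling for associated loci (mixed10
#'   defaults to 0.02; NA = unrestricted).
#' @return a [SimulationDesign-class].
#' @export
simulationDesign <- function(layout = "common25", n = 2000L, H = 10000L,
                             snpsPerRegion = 60L, assocRegions = NULL,
                             lociPerRegion = 3L, scenario = "I",
                             sigmaE = 0.1, mafLow = 0.05, mafHigh = 0.5,
                             mafDist = "uniform", rareMafMax = 0.01,
                             assocMafMax = NULL) {
  if (is.null(assocRegions))
    assocRegions <- if (layout == "mixed10") c(2L, 4L, 5L, 7L, 10L)
                    else integer(0)
  if (is.null(assocMafMax))
    assocMafMax <- if (layout == "mixed10") 0.02 else NA_real_
  new("SimulationDesign", layout = layout, n = as.integer(n),
      H = as.integer(H), snpsPerRegion = as.integer(snpsPerRegion),
      assocRegions = as.integer(assocRegions),
      lociPerRegion = as.integer(lociPerRegion), scenario = scenario,
      sigmaE = sigmaE, mafLow = mafLow, mafHigh = mafHigh,
      mafDist = mafDist, rareMafMax = rareMafMax, assocMafMax = assocMafMax)
}

#' Simulated haplotype pools
#'
#' `makeCommonPool` draws per-locus allele frequencies from
#' Uniform(mafLow, mafHigh) (or a truncated normal centered on the range) and
#' fills an `H x M` pool with independent Bernoulli haplotypes.
#' `makeRarePool` draws frequencies from a left-skewed Beta(0.5, 200) law
#' truncated to `(1/H, mafMax)`, builds a long pool of `poolLength` loci, and
#' returns a contiguous `M`-locus slice at a random offset — the analogue of
#' cutting a 5 kb segment out of a long simulated rare-variant panel.
#' Monomorphic pool columns are redrawn so every locus is polymorphic.
#'
#' @param M number of loci (for `makeRarePool`, the slice width).
#' @param H pool size (number of haplotypes).
#' @param mafLow,mafHigh common-variant frequency range.
#' @param mafDist "uniform" or "normal".
#' @param seed optional seed (NULL = use the current RNG stream).
#' @return a [HaplotypePool-class].
#' @export
makeCommonPool <- function(M, H = 10000L, mafLow = 0.05, mafHigh = 0.5,
                           mafDist = c("uniform", "normal"), seed = NULL) {
  mafDist <- match.arg(mafDist)
  if (!(mafLow > 0 && mafLow < mafHigh && mafHigh <= 0.5))
    stop("need 0 < mafLow < mafHigh <= 0.5")
  if (!is.null(seed)) set.seed(seed)
  freq <- if (mafDist == "uniform") runif(M, mafLow, mafHigh) else {
    mu <- (mafLow + mafHigh) / 2
    sdv <- (mafHigh - mafLow) / 4
    f <- rnorm(M, mu, sdv)
    while (any(bad <- f <= mafLow | f >= mafHigh))
      f[bad] <- rnorm(sum(bad), mu, sdv)
    f
  }
  haps <- matrix(rbinom(H * M, 1L, rep(freq, each = H)), H, M)
  haps <- redrawMonomorphic(haps, freq, H)
  new("HaplotypePool", haps = haps, targetMaf = freq, rare = FALSE)
}

redrawMonomorphic <- function(haps, freq, H) {
  for (j in seq_along(freq)) {
    tries <- 0L
    while (length(unique(haps[, j])) == 1L && tries < 100L) {
      haps[, j] <- rbinom(H, 1L, freq[j])
      tries <- tries + 1L
    }
    if (length(unique(haps[, j])) == 1L) {   # force one carrier
      haps[sample.int(H, 1L), j] <- 1L - haps[1L, j]
    }
  }
  haps
}

#' @rdname makeCommonPool
#' @param mafMax rare-variant frequency ceiling (must be <= 0.01).
#' @param poolLength length of the long pool that slices are cut from
#'   (default `10 * M`); `M > poolLength` is an error.
#' @param pool optionally, a pre-built long rare [HaplotypePool-class] to
#'   slice from (saves regenerating the panel for every region).
#' @export
makeRarePool <- function(M, H = 10000L, mafMax = 0.01,
                         poolLength = 10L * M, pool = NULL, seed = NULL) {
  if (mafMax > 0.01) stop("rare pools require mafMax <= 0.01")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- makeRarePanel(poolLength, H, mafMax)
  if (M > ncol(pool@haps)) stop("slice width exceeds the pool length")
  off <- sample.int(ncol(pool@haps) - M + 1L, 1L)
  sel <- off:(off + M - 1L)
  new("HaplotypePool", haps = pool@haps[, sel, drop = FALSE],
      targetMaf = pool@targetMaf[sel], rare = TRUE)
}

#' @rdname makeCommonPool
#' @export
makeRarePanel <- function(poolLength, H = 10000L, mafMax = 0.01) {
  freq <- numeric(poolLength)
  need <- seq_len(poolLength)
  while (length(need)) {                    # truncated Beta(0.5, 200)
    f <- stats::rbeta(length(need), 0.5, 200)
    ok <- f > 1 / H & f < mafMax
    freq[need[ok]] <- f[ok]
    need <- need[!ok]
  }
  haps <- matrix(rbinom(H * poolLength, 1L, rep(freq, each = H)),
                 H, poolLength)
  haps <- redrawMonomorphic(haps, freq, H)
  new("HaplotypePool", haps = haps, targetMaf = freq, rare = TRUE)
}

#' Haplotype pool with first-order linkage disequilibrium
#'
#' Builds haplotypes from a first-order Markov chain over loci whose
#' conditional allele probabilities are tuned so that the correlation between
#' adjacent loci is `sqrt(r2)`, with the per-pair target `r2` drawn uniformly
#' from `[r2Low, r2High]`. Marginal frequencies follow the common-variant
#' law. A target correlation that is infeasible for the drawn frequencies is
#' an error.
#'
#' @inheritParams makeCommonPool
#' @param r2Low,r2High adjacent-pair r-squared range (0 <= low <= high <= 1).
#' @return a [HaplotypePool-class].
#' @export
ldHaplotypes <- function(M, H = 10000L, r2Low = 0.25, r2High = 0.64,
                         mafLow = 0.05, mafHigh = 0.5, seed = NULL) {
  if (!(r2Low >= 0 && r2Low <= r2High && r2High <= 1))
    stop("need 0 <= r2Low <= r2High <= 1")
  if (!is.null(seed)) set.seed(seed)
  # frequencies drift slowly along the chain so that strong adjacent-pair
  # correlation stays attainable, as in real LD blocks
  freq <- numeric(M)
  freq[1L] <- runif(1L, mafLow, mafHigh)
  if (M > 1L) for (j in 2:M)
    freq[j] <- min(max(freq[j - 1L] + rnorm(1L, 0, 0.02), mafLow), mafHigh)
  haps <- matrix(0L, H, M)
  haps[, 1L] <- rbinom(H, 1L, freq[1L])
  if (M > 1L) for (j in 2:M) {
    rho <- sqrt(runif(1L, r2Low, r2High))
    qa <- freq[j - 1L]; qb <- freq[j]
    rhoMax <- min(sqrt(qa * (1 - qb) / (qb * (1 - qa))),
                  sqrt(qb * (1 - qa) / (qa * (1 - qb))))
    if (rhoMax^2 < r2Low)
      stop("target r2 infeasible for the drawn allele frequencies")
    rho <- min(rho, 0.999 * rhoMax)
    p1 <- qb + rho * sqrt(qb * (1 - qb) * (1 - qa) / qa)
    p0 <- qb - rho * sqrt(qb * (1 - qb) * qa / (1 - qa))
    haps[, j] <- rbinom(H, 1L, ifelse(haps[, j - 1L] == 1L, p1, p0))
  }
  new("HaplotypePool", haps = haps, targetMaf = freq, rare = FALSE)
}

#' Diploid genotypes from a haplotype pool
#'
#' Two independent uniform draws of haplotype indices per individual, summed
#' to additive 0/1/2 genotypes; Hardy-Weinberg holds marginally.
#'
#' @param pool a [HaplotypePool-class].
#' @param n number of diploid individuals (`n <= H`).
#' @param seed optional seed.
#' @return `n x M` genotype matrix.
#' @export
sampleDiploids <- function(pool, n, seed = NULL) {
  H <- nrow(pool@haps)
  if (n > H) stop("cannot sample more individuals than haplotypes")
  if (!is.null(seed)) set.seed(seed)
  i1 <- sample.int(H, n, replace = TRUE)
  i2 <- sample.int(H, n, replace = TRUE)
  G <- pool@haps[i1, , drop = FALSE] + pool@haps[i2, , drop = FALSE]
  storage.mode(G) <- "double"
  G
}

#' Assemble the multi-region genotype layout of a design
#'
#' Builds the genotype side of a [MultiRegionDataset] according to the
#' design's layout: `common25`/`rare25` splice 25 regions of one type;
#' `hybridI` splices 15 common and 10 rare regions in random order;
#' `hybridII` builds 25 rare regions and replaces a random 40% of each
#' region's columns with the paired common region's columns; `mixed10`
#' interleaves rare and common columns at fixed per-region rare-variant
#' proportions (0.7, 0.8, 0.6, 0.95, 0.9, 0.95, 0.7, 0.9, 0.8, 0.6) at
#' random positions. Region ids encode the region type.
#'
#' @param design a [SimulationDesign-class].
#' @param seed optional seed.
#' @return a [MultiRegionDataset] without trait.
#' @export
assembleMultiRegion <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- design@snpsPerRegion; H <- design@H; n <- design@n
  commonRegion <- function()
    sampleDiploids(makeCommonPool(M, H, design@mafLow, design@mafHigh,
                                  design@mafDist), n)
  rarePanel <- NULL
  rareRegion <- function() {
    if (is.null(rarePanel))
      rarePanel <<- makeRarePanel(10L * M, H, design@rareMafMax)
    sampleDiploids(makeRarePool(M, H, design@rareMafMax, pool = rarePanel), n)
  }
  mkRegions <- switch(design@layout,
    common25 = lapply(seq_len(25L), function(i)
      markerRegion(sprintf("common_%02d", i), commonRegion())),
    rare25 = lapply(seq_len(25L), function(i)
      markerRegion(sprintf("rare_%02d", i), rareRegion())),
    hybridI = {
      types <- sample(c(rep("common", 15L), rep("rare", 10L)))
      lapply(seq_len(25L), function(i) {
        X <- if (types[i] == "common") commonRegion() else rareRegion()
        markerRegion(sprintf("%s_%02d", types[i], i), X)
      })
    },
    hybridII = lapply(seq_len(25L), function(i) {
      Xr <- rareRegion(); Xc <- commonRegion()
      swap <- sample.int(M, round(0.4 * M))
      Xr[, swap] <- Xc[, swap]
      markerRegion(sprintf("hybrid2_%02d", i), Xr)
    }),
    mixed10 = {
      props <- c(0.7, 0.8, 0.6, 0.95, 0.9, 0.95, 0.7, 0.9, 0.8, 0.6)
      lapply(seq_len(10L), function(i) {
        nRare <- round(props[i] * M)
        rarePos <- sort(sample.int(M, nRare))
        Xr <- rareRegion(); Xc <- commonRegion()
        X <- Xc
        X[, rarePos] <- Xr[, seq_len(nRare)]
        markerRegion(sprintf("mixed_%02d", i), X)
      })
    },
    stop("unknown layout"))
  multiRegionDataset(mkRegions)
}

#' Effect magnitude from minor allele frequency
#'
#' The MAF-driven additive effect law `|beta| = |log10(2 MAF)| / 4 * 1.5`:
#' zero at MAF = 0.5, growing as the variant gets rarer (0.75 at MAF 0.005).
#'
#' @param maf folded frequency in (0, 0.5].
#' @return absolute effect value(s).
#' @examples
#' effectMagnitude(c(0.5, 0.05, 0.005))
#' @export
effectMagnitude <- function(maf) {
  if (any(maf <= 0)) stop("maf = 0 gives an infinite effect")
  if (any(maf > 0.5)) stop("maf must be <= 0.5")
  abs(log10(2 * maf)) / 4 * 1.5
}

#' Draw the associated loci and signed effects of one replicate
#'
#' Selects `lociPerRegion` eligible loci at random in every associated region
#' (eligible = polymorphic, and below `assocMafMax` when the design sets
#' one), assigns magnitudes by [effectMagnitude], and applies the scenario's
#' sign pattern: I all positive; II all loci flipped in two associated
#' regions (regions 4 and 7 for mixed10, a random two otherwise); III one
#' random locus flipped per region.
#'
#' @param design a [SimulationDesign-class].
#' @param dataset the assembled [MultiRegionDataset].
#' @param assocRegions associated region indices (defaults to the design's;
#'   must be non-empty).
#' @param seed optional seed.
#' @return data.frame with columns `region`, `locus`, `maf`, `beta`.
#' @export
assignEffects <- function(design, dataset, assocRegions = design@assocRegions,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(assocRegions)) stop("no associated regions specified")
  eff <- do.call(rbind, lapply(assocRegions, function(p) {
    maf <- dataset@regions[[p]]@maf
    elig <- which(maf > 0 & (is.na(design@assocMafMax) |
                             maf < design@assocMafMax))
    if (length(elig) < design@lociPerRegion)
      stop("region ", p, " has too few eligible associated loci")
    loci <- sort(sample(elig, design@lociPerRegion))
    data.frame(region = p, locus = loci, maf = maf[loci],
               beta = effectMagnitude(maf[loci]))
  }))
  if (design@scenario == "II") {
    neg <- if (design@layout == "mixed10") intersect(c(4L, 7L), assocRegions)
           else sample(assocRegions, 2L)
    eff$beta[eff$region %in% neg] <- -eff$beta[eff$region %in% neg]
  } else if (design@scenario == "III") {
    for (p in assocRegions) {
      rows <- which(eff$region == p)
      flip <- rows[sample.int(length(rows), 1L)]
      eff$beta[flip] <- -eff$beta[flip]
    }
  }
  eff
}

#' Simulate a quantitative trait under the additive model
#'
#' `y_i = sum_j x_ij beta_j + e_i` with `e ~ N(0, sigmaE^2)` over the
#' associated loci of `effects`; `nullTrait` draws pure-noise phenotypes
#' `N(0, sd = 0.1)` with no genetic term.
#'
#' @param dataset a [MultiRegionDataset].
#' @param effects effect table from [assignEffects].
#' @param sigmaE residual standard deviation.
#' @param seed optional seed.
#' @return numeric trait vector.
#' @export
simulateTrait <- function(dataset, effects, sigmaE = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nIndividuals(dataset)
  y <- rnorm(n, 0, sigmaE)
  for (k in seq_len(nrow(effects)))
    y <- y + dataset@regions[[effects$region[k]]]@X[, effects$locus[k]] *
      effects$beta[k]
  y
}

#' @rdname simulateTrait
#' @param n number of individuals.
#' @param sigma noise standard deviation of the null phenotype.
#' @export
nullTrait <- function(n, sigma = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, 0, sigma)
}

#' Generate one complete simulated study replicate
#'
#' Convenience wrapper: assembles the layout, draws associated regions when
#' the design leaves them random, assigns effects, and simulates the trait.
#' Fully reproducible from `seed`.
#'
#' @param design a [SimulationDesign-class].
#' @param seed integer seed for the replicate.
#' @return list with `dataset` (trait attached), `effects`, `assoc`
#'   (associated region indices), and `design`.
#' @export
simulateStudy <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dataset <- assembleMultiRegion(design)
  assoc <- design@assocRegions
  if (!length(assoc))
    assoc <- sort(sample.int(nRegions(dataset), 5L))
  effects <- assignEffects(design, dataset, assocRegions = assoc)
  trait(dataset) <- simulateTrait(dataset, effects, design@sigmaE)
  list(dataset = dataset, effects = effects, assoc = assoc, design = design)
}
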