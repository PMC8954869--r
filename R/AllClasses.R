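#' @import methods
#' @importFrom stats dbeta pf rnorm runif rbinom sd var coef
NULL

#' Orthonormal Fourier basis on a genomic interval
#'
#' A system of `K` orthonormal Fourier basis functions on `[0, T]`, evaluated
#' at an ordered grid of marker positions. The first basis function is the
#' constant `1/sqrt(T)`; subsequent functions come in sine/cosine pairs
#' `sqrt(2/T) sin(2 pi k t / T)`, `sqrt(2/T) cos(2 pi k t / T)`. The system is
#' exactly orthonormal under the continuous inner product on `[0, T]`.
#'
#' @slot K integer, number of basis functions (>= 1).
#' @slot T numeric, domain length (default 1; the genomic interval is always
#'   rescaled to `[0, T]`).
#' @slot evalPoints numeric, strictly increasing marker positions in `[0, T]`.
#' @export
setClass("FourierBasis",
  representation(K = "integer", T = "numeric", evalPoints = "numeric"),
  prototype(K = 25L, T = 1, evalPoints = numeric(0))
)

setValidity("FourierBasis", function(object) {
  msg <- character(0)
  if (length(object@K) != 1L || object@K < 1L)
    msg <- c(msg, "K must be a single integer >= 1")
  if (length(object@T) != 1L || object@T <= 0)
    msg <- c(msg, "T must be a single positive number")
  p <- object@evalPoints
  if (length(p)) {
    if (any(p < 0) || any(p > object@T))
      msg <- c(msg, "evalPoints must lie within [0, T]")
    if (length(p) > 1L && any(diff(p) <= 0))
      msg <- c(msg, "evalPoints must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' One gene region of additive genotypes
#'
#' Holds the `n x M` additive genotype matrix (0/1/2 minor-allele counts) of a
#' single gene region, the ordered marker coordinates, and the per-locus
#' folded minor allele frequencies.
#'
#' @slot regionId character label.
#' @slot positions numeric, M ordered marker coordinates.
#' @slot X numeric matrix, n individuals x M markers, entries in {0, 1, 2}.
#' @slot maf numeric, M folded allele frequencies in [0, 0.5].
#' @export
setClass("MarkerRegion",
  representation(regionId = "character", positions = "numeric",
                 X = "matrix", maf = "numeric")
)

setValidity("MarkerRegion", function(object) {
  msg <- character(0)
  M <- ncol(object@X)
  if (M < 1L) msg <- c(msg, "region must contain at least one marker")
  if (length(object@positions) != M)
    msg <- c(msg, "positions length must equal ncol(X)")
  if (length(object@maf) != M)
    msg <- c(msg, "maf length must equal ncol(X)")
  if (length(object@maf) && (any(object@maf < 0) || any(object@maf > 0.5)))
    msg <- c(msg, "maf must lie in [0, 0.5]")
  if (length(object@X) && !all(object@X %in% c(0, 1, 2)))
    msg <- c(msg, "genotypes must be additive codes in {0, 1, 2}")
  if (M > 1L && any(diff(object@positions) < 0))
    msg <- c(msg, "positions must be ordered")
  if (length(msg)) msg else TRUE
})

#' Multi-region genotype dataset with a quantitative trait
#'
#' An ordered collection of [MarkerRegion] objects sharing `n` individuals,
#' together with the trait vector `y` those individuals were phenotyped for.
#'
#' @slot regions list of [MarkerRegion] objects (P >= 1).
#' @slot y numeric trait vector of length n (may be length 0 before a trait
#'   is attached).
#' @export
setClass("MultiRegionDataset",
  representation(regions = "list", y = "numeric")
)

setValidity("MultiRegionDataset", function(object) {
  msg <- character(0)
  if (!length(object@regions)) msg <- c(msg, "need at least one region")
  ok <- vapply(object@regions, is, logical(1), class2 = "MarkerRegion")
  if (!all(ok)) msg <- c(msg, "regions must all be MarkerRegion objects")
  if (all(ok) && length(object@regions)) {
    ns <- vapply(object@regions, function(r) nrow(r@X), integer(1))
    if (length(unique(ns)) != 1L)
      msg <- c(msg, "all regions must share the same number of individuals")
    if (length(object@y) && length(object@y) != ns[1L])
      msg <- c(msg, "trait length must equal the number of individuals")
  }
  if (length(msg)) msg else TRUE
})

#' Per-locus Beta-density weighting scheme
#'
#' Weights each locus by the Beta(a1, a2) density evaluated at its folded
#' minor allele frequency, the convention used to upweight rare variants.
#' `a1 = a2 = 1` gives uniform weights (no weighting).
#'
#' @slot a1,a2 positive Beta shape parameters.
#' @export
setClass("LocusWeightScheme",
  representation(a1 = "numeric", a2 = "numeric"),
  prototype(a1 = 1, a2 = 10)
)

setValidity("LocusWeightScheme", function(object) {
  if (length(object@a1) != 1L || length(object@a2) != 1L ||
      object@a1 <= 0 || object@a2 <= 0)
    "a1 and a2 must be single positive numbers" else TRUE
})

#' Tuning parameters for the locally sparse functional regression
#'
#' @slot gamma numeric, per-region roughness-penalty weights (recycled to P).
#' @slot lam numeric, per-region fSCAD sparsity weights ("compression
#'   parameters", recycled to P).
#' @slot scadA SCAD shape parameter (> 2, conventionally 3.7).
#' @slot splineOrder B-spline order of the effect basis (4 = cubic).
#' @slot m derivative order of the roughness penalty (default 2).
#' @slot maxIter,tol iteration cap and relative-change convergence tolerance
#'   of the local quadratic approximation loop.
#' @slot nullTol relative threshold below which a subinterval's fSCAD
#'   argument is treated as null (scaled by the region's lambda).
#' @slot sseRefit "penalized" or "ols": how the nested residual sums of
#'   squares of the adjusted partial F test are recomputed.
#' @slot standardize scale each region's design block to unit average column
#'   variance before penalization (the usual penalized-regression
#'   convention; a single scalar per region, so effect functions keep their
#'   shape and are back-transformed after fitting).
#' @slot scadGroups "subinterval" applies the fSCAD argument per knot
#'   subinterval; "support" applies it per basis-coefficient support.
#' @export
setClass("SLoSConfig",
  representation(gamma = "numeric", lam = "numeric", scadA = "numeric",
                 splineOrder = "integer", m = "integer", maxIter = "integer",
                 tol = "numeric", nullTol = "numeric", sseRefit = "character",
                 standardize = "logical", scadGroups = "character"),
  prototype(gamma = 0.1, lam = 0.1, scadA = 3.7, splineOrder = 4L, m = 2L,
            maxIter = 50L, tol = 1e-4, nullTol = 1e-3, sseRefit = "ols",
            standardize = TRUE, scadGroups = "subinterval")
)

setValidity("SLoSConfig", function(object) {
  msg <- character(0)
  if (any(object@gamma < 0)) msg <- c(msg, "gamma must be >= 0")
  if (any(object@lam < 0)) msg <- c(msg, "lam must be >= 0")
  if (object@scadA <= 2) msg <- c(msg, "scadA must exceed 2")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (object@splineOrder < 1L) msg <- c(msg, "splineOrder must be >= 1")
  if (!object@sseRefit %in% c("penalized", "ols"))
    msg <- c(msg, "sseRefit must be 'penalized' or 'ols'")
  if (!object@scadGroups %in% c("subinterval", "support"))
    msg <- c(msg, "scadGroups must be 'subinterval' or 'support'")
  if (length(msg)) msg else TRUE
})

#' Fitted locally sparse multi-region functional regression
#'
#' @slot mu0 intercept estimate.
#' @slot coef list of per-region effect-basis coefficient vectors (exact
#'   zeros where compressed).
#' @slot nullCoefMask list of per-region logical vectors, TRUE where the
#'   coefficient was compressed to null.
#' @slot nullRegionMask logical, TRUE for regions whose whole effect function
#'   was compressed to null.
#' @slot rss residual sum of squares of the fit.
#' @slot nIter iterations used; @slot converged convergence flag.
#' @slot regionIds character, region labels in fitting order.
#' @export
setClass("SLoSFit",
  representation(mu0 = "numeric", coef = "list", nullCoefMask = "list",
                 nullRegionMask = "logical", rss = "numeric",
                 nIter = "integer", converged = "logical",
                 regionIds = "character")
)

setValidity("SLoSFit", function(object) {
  msg <- character(0)
  allnull <- vapply(object@nullCoefMask, all, logical(1))
  if (length(allnull) && !identical(unname(allnull),
                                    unname(object@nullRegionMask)))
    msg <- c(msg, "nullRegionMask must equal all(nullCoefMask) per region")
  zero_ok <- mapply(function(b, m) all(b[m] == 0),
                    object@coef, object@nullCoefMask)
  if (length(zero_ok) && !all(zero_ok))
    msg <- c(msg, "coefficients flagged null must be exactly 0")
  if (length(msg)) msg else TRUE
})

#' Pool of simulated haplotypes
#'
#' @slot haps H x M binary haplotype matrix.
#' @slot targetMaf numeric, per-locus target allele frequencies.
#' @slot rare logical, TRUE when generated under the rare-variant law.
#' @export
setClass("HaplotypePool",
  representation(haps = "matrix", targetMaf = "numeric", rare = "logical"),
  prototype(rare = FALSE)
)

setValidity("HaplotypePool", function(object) {
  msg <- character(0)
  if (length(object@targetMaf) != ncol(object@haps))
    msg <- c(msg, "targetMaf length must equal ncol(haps)")
  if (length(object@haps) && !all(object@haps %in% c(0, 1)))
    msg <- c(msg, "haplotypes must be binary")
  if (length(msg)) msg else TRUE
})

#' Simulation design for a multi-gene-region study
#'
#' Encodes one of the study layouts: `rare25` (25 rare-variant regions),
#' `common25` (25 common-variant regions), `hybridI` (15 common + 10 rare
#' regions in random order), `hybridII` (25 regions, each 60% rare / 40%
#' common columns), or `mixed10` (10 regions mixing rare and common variants
#' at fixed per-region proportions).
#'
#' @slot layout one of "rare25", "common25", "hybridI", "hybridII", "mixed10".
#' @slot n number of diploid individuals (default 2000).
#' @slot H haplotype-pool size (default 10000).
#' @slot snpsPerRegion markers per region (default 60).
#' @slot assocRegions integer indices of associated regions.
#' @slot lociPerRegion associated loci drawn per associated region (default 3).
#' @slot scenario effect-sign scenario "I", "II" or "III".
#' @slot sigmaE residual standard deviation of the trait model (default 0.1).
#' @slot mafLow,mafHigh common-variant allele-frequency range.
#' @slot mafDist "uniform" or "normal" law for common-variant frequencies.
#' @slot rareMafMax rare-variant frequency ceiling (default 0.01).
#' @slot assocMafMax frequency ceiling for eligible associated loci (NA =
#'   no restriction; the mixed10 layout uses 0.02).
#' @export
setClass("SimulationDesign",
  representation(layout = "character", n = "integer", H = "integer",
                 snpsPerRegion = "integer", assocRegions = "integer",
                 lociPerRegion = "integer", scenario = "character",
                 sigmaE = "numeric", mafLow = "numeric", mafHigh = "numeric",
                 mafDist = "character", rareMafMax = "numeric",
                 assocMafMax = "numeric"),
  prototype(layout = "common25", n = 2000L, H = 10000L, snpsPerRegion = 60L,
            assocRegions = integer(0), lociPerRegion = 3L, scenario = "I",
            sigmaE = 0.1, mafLow = 0.05, mafHigh = 0.5, mafDist = "uniform",
            rareMafMax = 0.01, assocMafMax = NA_real_)
)

setValidity("SimulationDesign", function(object) {
  msg <- character(0)
  if (!object@layout %in% c("rare25", "common25", "hybridI", "hybridII",
                            "mixed10"))
    msg <- c(msg, "unknown layout")
  if (!object@scenario %in% c("I", "II", "III"))
    msg <- c(msg, "scenario must be 'I', 'II' or 'III'")
  P <- if (object@layout == "mixed10") 10L else 25L
  if (length(object@assocRegions) &&
      (any(object@assocRegions < 1L) || any(object@assocRegions > P)))
    msg <- c(msg, "assocRegions out of range for layout")
  if (object@n < 1L || object@H < 1L || object@n > object@H)
    msg <- c(msg, "need 1 <= n <= H")
  if (!(object@mafLow > 0 && object@mafLow < object@mafHigh &&
        object@mafHigh <= 0.5))
    msg <- c(msg, "need 0 < mafLow < mafHigh <= 0.5")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FourierBasis", function(object) {
  cat("FourierBasis:", object@K, "orthonormal functions on [0,",
      object@T, "],", length(object@evalPoints), "evaluation points\n")
})

setMethod("show", "MarkerRegion", function(object) {
  cat("MarkerRegion '", object@regionId, "': ", nrow(object@X),
      " individuals x ", ncol(object@X), " markers, MAF range [",
      signif(min(object@maf), 3), ", ", signif(max(object@maf), 3), "]\n",
      sep = "")
})

setMethod("show", "MultiRegionDataset", function(object) {
  cat("MultiRegionDataset:", length(object@regions), "regions,",
      nrow(object@regions[[1L]]@X), "individuals,",
      if (length(object@y)) "trait attached" else "no trait", "\n")
  m <- vapply(object@regions, function(r) ncol(r@X), integer(1))
  cat("  markers per region:", paste(range(m), collapse = "-"), "\n")
})

setMethod("show", "SLoSFit", function(object) {
  cat("SLoSFit:", length(object@coef), "regions,",
      sum(!object@nullRegionMask), "non-null;",
      "rss =", signif(object@rss, 6), "\n")
  cat("  converged:", object@converged, "in", object@nIter, "iterations\n")
})

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@layout, "layout, n =", object@n,
      ", scenario", object@scenario, "\n")
  cat("  associated regions:", paste(object@assocRegions, collapse = ", "),
      "(", object@lociPerRegion, "loci each )\n")
})
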