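#' Constructors and accessors for the core data classes
#'
#' `markerRegion()` builds a [MarkerRegion] from a genotype matrix (MAFs are
#' computed with [computeMAF] unless supplied); `multiRegionDataset()` bundles
#' regions with an optional trait; `fourierBasis()` builds a [FourierBasis].
#'
#' @param regionId character label.
#' @param X n x M additive genotype matrix with entries in {0, 1, 2}.
#' @param positions optional marker coordinates; defaults to the ordinal
#'   index mapped to the unit interval.
#' @param maf optional per-locus folded frequencies; computed from `X` when
#'   missing.
#' @return `markerRegion()` a [MarkerRegion]; `multiRegionDataset()` a
#'   [MultiRegionDataset]; `fourierBasis()` a [FourierBasis].
#' @examples
#' r <- markerRegion("g1", matrix(c(0, 1, 2, 0, 1, 1), nrow = 3))
#' d <- multiRegionDataset(list(r), y = c(0.2, -0.1, 0.4))
#' nRegions(d)
#' @export
markerRegion <- function(regionId, X, positions = NULL, maf = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(positions)) positions <- seq_len(ncol(X))
  if (is.null(maf)) maf <- computeMAF(X)
  new("MarkerRegion", regionId = as.character(regionId),
      positions = as.numeric(positions), X = X, maf = maf)
}

#' @rdname markerRegion
#' @param regions list of [MarkerRegion] objects.
#' @param y numeric trait vector (optional).
#' @export
multiRegionDataset <- function(regions, y = numeric(0)) {
  new("MultiRegionDataset", regions = regions, y = as.numeric(y))
}

#' @rdname markerRegion
#' @param K number of Fourier basis functions.
#' @param evalPoints evaluation grid in `[0, T]`; defaults to `M` equispaced
#'   points when `M` is given.
#' @param T domain length.
#' @param M shorthand: number of equispaced evaluation points.
#' @export
fourierBasis <- function(K = 25L, evalPoints = NULL, T = 1, M = NULL) {
  if (is.null(evalPoints)) {
    if (is.null(M)) stop("supply evalPoints or M")
    evalPoints <- if (M == 1L) T / 2 else seq(0, T, length.out = M)
  }
  new("FourierBasis", K = as.integer(K), T = as.numeric(T),
      evalPoints = as.numeric(evalPoints))
}

#' @rdname markerRegion
#' @param x a [MultiRegionDataset].
#' @export
nRegions <- function(x) length(x@regions)

#' @rdname markerRegion
#' @export
nIndividuals <- function(x) nrow(x@regions[[1L]]@X)

#' @rdname markerRegion
#' @export
regionIds <- function(x) vapply(x@regions, function(r) r@regionId,
                                character(1))

#' @rdname markerRegion
#' @export
trait <- function(x) x@y

#' @rdname markerRegion
#' @param value replacement trait vector.
#' @export
`trait<-` <- function(x, value) {
  x@y <- as.numeric(value)
  validObject(x)
  x
}

#' @rdname markerRegion
#' @param region region index or id.
#' @export
getRegion <- function(x, region) {
  if (is.character(region)) region <- match(region, regionIds(x))
  x@regions[[region]]
}

#' @rdname markerRegion
#' @export
genotypes <- function(x, region) getRegion(x, region)@X

#' @rdname markerRegion
#' @export
regionMAF <- function(x, region) getRegion(x, region)@maf
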