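# Step and LW-Step: each region's Fourier coefficient block enters a linear
# model as one grouped variable; backward (or forward) stepwise AIC selection
# over blocks, then block partial F tests on the surviving model.

#' Per-region functional design blocks
#'
#' Smooths each region's genotype matrix (optionally after Beta-density locus
#' weighting) onto `K` orthonormal Fourier basis functions evaluated at the
#' region's marker grid, returning one `n x K` coefficient block per region.
#' With identical orthonormal genotype and effect bases the basis
#' cross-product is the identity, so these blocks are exactly the regression
#' design of the functional multi-region linear model.
#'
#' @param dataset a [MultiRegionDataset].
#' @param K number of Fourier basis functions per region (default 25).
#' @param lambda_x smoothing penalty weight (default 0).
#' @param weights optional [LocusWeightScheme]; when given, genotypes are
#'   column-scaled by Beta-density MAF weights before smoothing (the LW
#'   variants).
#' @param positions "ordinal" maps marker j to `(j-1)/(M-1)` on the unit
#'   interval; "physical" rescales the stored coordinates affinely to [0, 1].
#' @return named list of `n x K` numeric matrices, one per region.
#' @export
regionDesignBlocks <- function(dataset, K = 25L, lambda_x = 0, weights = NULL,
                               positions = c("ordinal", "physical")) {
  positions <- match.arg(positions)
  lapply(stats::setNames(dataset@regions, regionIds(dataset)), function(r) {
    M <- ncol(r@X)
    pts <- if (positions == "physical" && M > 1L) {
      p <- r@positions
      (p - p[1L]) / (p[M] - p[1L])
    } else if (M == 1L) 0.5 else (seq_len(M) - 1) / (M - 1)
    b <- fourierBasis(K = K, evalPoints = pts)
    X <- if (is.null(weights)) r@X
         else applyLocusWeights(r, betaLocusWeights(r@maf, weights))
    smoothGenotypeRegion(X, b, lambda_x)$d
  })
}

#' Akaike information criterion for a residual sum of squares
#'
#' `AIC = n ln(Rss/n) + 2 K`, where `K` counts the regression coefficients of
#' the active region blocks (the intercept is not counted).
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of individuals.
#' @param K total count of coefficients in the active blocks.
#' @return the criterion value; `-Inf` (perfect fit) when `rss <= 0`.
#' @export
aicValue <- function(rss, n, K) {
  if (rss <= 0) {
    warning("rss <= 0: perfect-fit condition, AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * K
}

# Cross-product bookkeeping for fast subset RSS. Intercept is absorbed by
# centering y and the design columns. Returns a closure environment.
blockRegression <- function(y, blocks) {
  n <- length(y)
  Z <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  colIdx <- split(seq_len(sum(sizes)), rep(seq_along(blocks), sizes))
  yc <- y - mean(y)
  Zc <- sweep(Z, 2L, colMeans(Z))
  list(n = n, P = length(blocks), sizes = sizes, colIdx = colIdx,
       ids = names(blocks), C = crossprod(Zc), cy = drop(crossprod(Zc, yc)),
       yy = sum(yc^2))
}

# Projection RSS of y on the intercept + the given blocks, robust to rank
# deficiency via pivoted Cholesky.
rssForBlocks <- function(br, active) {
  if (!length(active)) return(br$yy)
  cols <- unlist(br$colIdx[active], use.names = FALSE)
  Cs <- br$C[cols, cols, drop = FALSE]
  cys <- br$cy[cols]
  R <- suppressWarnings(chol(Cs, pivot = TRUE))
  piv <- attr(R, "pivot")
  dR <- abs(diag(R))
  rank <- attr(R, "rank")
  while (rank > 0L && dR[rank] <= max(dR) * 1e-9) rank <- rank - 1L
  if (rank == 0L) return(br$yy)
  u <- forwardsolve(t(R[seq_len(rank), seq_len(rank), drop = FALSE]),
                    cys[piv[seq_len(rank)]])
  max(br$yy - sum(u^2), 0)
}

#' Backward (or forward) stepwise AIC selection over region blocks
#'
#' Starting from the model containing every region block (backward) or none
#' (forward), repeatedly deletes (adds) the whole block whose removal
#' (addition) gives the smallest AIC, as long as that AIC improves on the
#' current model; ties are broken toward the lowest region index. Each step
#' refits ordinary least squares with an intercept. Terminates at a local
#' AIC minimum.
#'
#' @param y trait vector.
#' @param blocks named list of `n x K` region design blocks (from
#'   [regionDesignBlocks]).
#' @param direction "backward" (default) or "forward".
#' @return object of class `StepModel`: list with `active` (indices of
#'   retained regions), `ids`, `rss`, `aic`, `K` (coefficients in the model),
#'   `n`, and the internal regression state used by [partialFTest].
#' @export
backwardStepwise <- function(y, blocks, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  br <- blockRegression(y, blocks)
  fullK <- sum(br$sizes)
  if (direction == "backward" && br$n <= fullK + 1L)
    stop("need n > total coefficients + 1 for the full model")
  if (direction == "backward") {
    Rfull <- suppressWarnings(chol(br$C, pivot = TRUE))
    dR <- abs(diag(Rfull))
    if (sum(dR > max(dR) * 1e-9) < fullK)
      warning("rank-deficient full design; projection fits are used")
    active <- seq_len(br$P)
  } else active <- integer(0)
  repeat {
    curRss <- rssForBlocks(br, active)
    curAic <- aicValue(curRss, br$n, sum(br$sizes[active]))
    cand <- if (direction == "backward") active
            else setdiff(seq_len(br$P), active)
    if (!length(cand)) break
    aics <- NULL
    if (direction == "backward") {
      # drop-one RSS via the partitioned-inverse identity:
      # RSS_{-S} = RSS + beta_S' (Cinv_SS)^{-1} beta_S
      cols <- unlist(br$colIdx[active], use.names = FALSE)
      blk <- rep(active, br$sizes[active])
      ch <- tryCatch(chol(br$C[cols, cols, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(ch) && min(diag(ch)) > max(diag(ch)) * 1e-7) {
        Cinv <- chol2inv(ch)
        beta <- Cinv %*% br$cy[cols]
        aics <- vapply(cand, function(p) {
          s <- which(blk == p)
          quad <- tryCatch(
            drop(crossprod(beta[s],
                           solve(Cinv[s, s, drop = FALSE], beta[s]))),
            error = function(e) NA_real_)
          if (is.na(quad))    # ill-conditioned sub-block: exact projection
            return(aicValue(rssForBlocks(br, setdiff(active, p)), br$n,
                            sum(br$sizes[setdiff(active, p)])))
          aicValue(curRss + max(quad, 0), br$n,
                   sum(br$sizes[setdiff(active, p)]))
        }, numeric(1))
      }
    }
    if (is.null(aics))                # rank-deficient or forward path
      aics <- vapply(cand, function(p) {
        trial <- if (direction == "backward") setdiff(active, p)
                 else c(active, p)
        aicValue(rssForBlocks(br, trial), br$n, sum(br$sizes[trial]))
      }, numeric(1))
    best <- which.min(aics)           # which.min takes the first = lowest index
    if (aics[best] < curAic) {
      active <- if (direction == "backward") setdiff(active, cand[best])
                else sort(c(active, cand[best]))
    } else break
  }
  rss <- rssForBlocks(br, active)
  structure(list(active = active, ids = br$ids[active], rss = rss,
                 aic = aicValue(rss, br$n, sum(br$sizes[active])),
                 K = sum(br$sizes[active]), n = br$n, br = br),
            class = "StepModel")
}

#' @export
print.StepModel <- function(x, ...) {
  cat("StepModel:", length(x$active), "of", x$br$P, "regions retained;",
      "AIC =", signif(x$aic, 6), "\n")
  invisible(x)
}

#' Block partial F test within a stepwise model
#'
#' Tests one retained region by the nested-model partial F statistic
#' `F = [(SSE_reduced - SSE_full)/q] / [SSE_full/(n - K_full - 1)]`, where
#' `q` is the number of coefficients in the tested block and `K_full` the
#' total coefficient count of the selected model; the p-value comes from the
#' `F(q, n - K_full - 1)` distribution.
#'
#' @param model a `StepModel` from [backwardStepwise].
#' @param region region index or id; must be in the active set.
#' @return one-row data.frame with `region_id`, `selected`, `F`, `df1`,
#'   `df2`, `p_value`.
#' @export
partialFTest <- function(model, region) {
  br <- model$br
  if (is.character(region)) region <- match(region, br$ids)
  if (!region %in% model$active)
    stop("region is not in the selected model")
  q <- br$sizes[region]
  df2 <- br$n - model$K - 1L
  if (df2 <= 0) stop("no residual degrees of freedom")
  sseRed <- rssForBlocks(br, setdiff(model$active, region))
  Fstat <- ((sseRed - model$rss) / q) / (model$rss / df2)
  Fstat <- max(Fstat, 0)
  data.frame(region_id = br$ids[region], selected = TRUE, F = Fstat,
             df1 = q, df2 = df2,
             p_value = pf(Fstat, q, df2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' The Step / LW-Step multi-gene-region association test
#'
#' Full pipeline: smooth each region onto `K` Fourier basis functions
#' (optionally after locus weighting — the LW-Step variant), select regions
#' by backward stepwise AIC over whole coefficient blocks, then assign each
#' retained region a block partial F p-value. Regions deleted during
#' selection are reported with `selected = FALSE` and `p_value = 1`.
#'
#' @inheritParams regionDesignBlocks
#' @inheritParams backwardStepwise
#' @return data.frame with one row per region: `region_id`, `selected`, `F`,
#'   `df1`, `df2`, `p_value`.
#' @examples
#' d <- simulateStudy(simulationDesign("common25", n = 200,
#'                    snpsPerRegion = 12, assocRegions = 1:2), seed = 1)
#' stepTest(d$dataset, K = 7)[1:3, ]
#' @export
stepTest <- function(dataset, K = 25L, lambda_x = 0, weights = NULL,
                     direction = "backward") {
  blocks <- regionDesignBlocks(dataset, K = K, lambda_x = lambda_x,
                               weights = weights)
  model <- backwardStepwise(dataset@y, blocks, direction = direction)
  res <- do.call(rbind, lapply(seq_along(blocks), function(p) {
    if (p %in% model$active) partialFTest(model, p)
    else data.frame(region_id = names(blocks)[p], selected = FALSE,
                    F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                    p_value = 1, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Single-region functional F test (FLM-style baseline)
#'
#' Tests each region separately by the overall F test of the trait on the
#' region's Fourier coefficient block — the population functional linear
#' model applied one region at a time. Used as the single-region comparator
#' for the multi-region methods.
#'
#' @inheritParams regionDesignBlocks
#' @return data.frame with one row per region (`selected` is TRUE for all).
#' @export
singleRegionFTest <- function(dataset, K = 25L, lambda_x = 0,
                              weights = NULL) {
  blocks <- regionDesignBlocks(dataset, K = K, lambda_x = lambda_x,
                               weights = weights)
  y <- dataset@y
  res <- do.call(rbind, lapply(names(blocks), function(id) {
    br <- blockRegression(y, blocks[id])
    sse <- rssForBlocks(br, 1L)
    q <- br$sizes[1L]
    df2 <- br$n - q - 1L
    Fstat <- max(((br$yy - sse) / q) / (sse / df2), 0)
    data.frame(region_id = id, selected = TRUE, F = Fstat, df1 = q,
               df2 = df2, p_value = pf(Fstat, q, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
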