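# Multi-SLoS, W-SLoS and LW-SLoS: locally sparse functional regression of a
# quantitative trait on smoothed multi-region genotype functions. The loss is
#   (1/n) sum_i (y_i - mu0 - sum_p int X_pi beta_p)^2
#     + sum_p gamma_p ||D^m beta_p||^2
#     + sum_p (M_p/T) int p_lambda_p(|beta_p(t)|) dt
# with the fSCAD term approximated per knot subinterval by the SCAD function
# of the local root-mean-square of beta_p, and minimized by local quadratic
# approximation (iteratively reweighted generalized ridge). Subintervals whose
# fSCAD argument collapses are declared null; B-spline coefficients whose
# whole support is null are frozen at exactly zero.

#' SCAD penalty function
#'
#' The smoothly clipped absolute deviation penalty: `lam * u` for
#' `u <= lam`; quadratic blending `-(u^2 - 2 a lam u + lam^2)/(2(a-1))` for
#' `lam < u <= a lam`; constant `(a+1) lam^2 / 2` beyond `a lam`. Continuous
#' with continuous first derivative at both knots.
#'
#' @param u nonnegative magnitude(s).
#' @param lam penalty level (>= 0).
#' @param a shape parameter (> 2; conventionally 3.7).
#' @return penalty value(s).
#' @examples
#' scadPenalty(c(0, 1, 10), lam = 1, a = 3.7)
#' @export
scadPenalty <- function(u, lam, a = 3.7) {
  if (a <= 2) stop("SCAD shape parameter a must exceed 2")
  if (any(u < 0) || lam < 0) stop("u and lam must be nonnegative")
  ifelse(u <= lam, lam * u,
         ifelse(u <= a * lam,
                -(u^2 - 2 * a * lam * u + lam^2) / (2 * (a - 1)),
                (a + 1) * lam^2 / 2))
}

#' @describeIn scadPenalty First derivative of the SCAD penalty.
#' @export
scadDerivative <- function(u, lam, a = 3.7) {
  if (a <= 2) stop("SCAD shape parameter a must exceed 2")
  ifelse(u <= lam, lam,
         ifelse(u <= a * lam, (a * lam - u) / (a - 1), 0))
}

#' @rdname fitMultiSLoS
#' @param gamma,lam per-region (or scalar) roughness and compression weights.
#' @param ... further slots of [SLoSConfig-class] (`scadA`, `m`, `maxIter`,
#'   `tol`, `nullTol`, `sseRefit`, `splineOrder`).
#' @export
slosConfig <- function(gamma = 0.1, lam = 0.1, ...) {
  new("SLoSConfig", gamma = gamma, lam = lam, ...)
}

#' Region-type weighted SLoS configuration
#'
#' Builds a [SLoSConfig-class] whose per-region smoothing (`gamma`) and
#' compression (`lam`) parameters depend on the region type, the W-SLoS
#' device for putting rare- and common-variant regions on an equal footing.
#' Defaults follow the weighted-method study: common regions (0.02, 0.05),
#' rare regions (0.01, 0.0025).
#'
#' @param commonRegions,rareRegions disjoint integer index sets covering
#'   regions 1..P.
#' @param common,rare length-2 vectors `c(gamma, lam)` per region type.
#' @param ... passed to [slosConfig].
#' @return a [SLoSConfig-class] with per-region `gamma` and `lam`.
#' @export
wslosConfig <- function(commonRegions, rareRegions,
                        common = c(gamma = 0.02, lam = 0.05),
                        rare = c(gamma = 0.01, lam = 0.0025), ...) {
  if (length(intersect(commonRegions, rareRegions)))
    stop("commonRegions and rareRegions must be disjoint")
  P <- length(commonRegions) + length(rareRegions)
  if (!setequal(c(commonRegions, rareRegions), seq_len(P)))
    stop("region ids must cover 1..P")
  gamma <- numeric(P); lam <- numeric(P)
  gamma[commonRegions] <- common[1L]; lam[commonRegions] <- common[2L]
  gamma[rareRegions] <- rare[1L]; lam[rareRegions] <- rare[2L]
  slosConfig(gamma = gamma, lam = lam, ...)
}

# B-spline effect basis of one region: order-`ord` splines with knots at the
# marker grid in marker-index units (domain [0, M-1], unit knot spacing --
# the scale on which the study's gamma/lambda magnitudes operate). Returns
# design pieces for the quadrature grid: basis values, m-th derivatives,
# subinterval membership.
effectBasisPieces <- function(M, ord, m) {
  if (M < 2L) stop("a region needs at least 2 markers for the effect basis")
  inner <- seq(0, M - 1)
  knots <- c(rep(inner[1L], ord - 1L), inner, rep(inner[M], ord - 1L))
  Kb <- M + ord - 2L
  quad <- subintervalQuadrature(inner)
  B <- splines::splineDesign(knots, quad$nodes, ord = ord)
  Bm <- splines::splineDesign(knots, quad$nodes, ord = ord,
                              derivs = rep(m, length(quad$nodes)))
  list(knots = knots, inner = inner, Kb = Kb, quad = quad, B = B, Bm = Bm,
       ord = ord)
}

# Assemble the quadratic pieces of the SLoS objective for one dataset.
buildSLoSProblem <- function(dataset, K, config, lambda_x = 0,
                             weights = NULL) {
  P <- nRegions(dataset)
  n <- nIndividuals(dataset)
  gamma <- rep_len(config@gamma, P)
  lam <- rep_len(config@lam, P)
  ord <- config@splineOrder
  y <- dataset@y
  if (!length(y)) stop("dataset carries no trait")
  blocks <- vector("list", P)
  Rm <- vector("list", P); Vsub <- vector("list", P)
  Kbs <- integer(P); Ms <- integer(P)
  for (p in seq_len(P)) {
    r <- dataset@regions[[p]]
    M <- ncol(r@X); Ms[p] <- M
    pts <- seq(0, M - 1)                    # marker-index units, T = M - 1
    fb <- fourierBasis(K = K, evalPoints = pts, T = M - 1)
    X <- if (is.null(weights)) r@X
         else applyLocusWeights(r, betaLocusWeights(r@maf, weights))
    D <- smoothGenotypeRegion(X, fb, lambda_x)$d
    eb <- effectBasisPieces(M, ord, config@m)
    Kbs[p] <- eb$Kb
    wq <- eb$quad$weights
    PhiQ <- evalFourierBasis(K, eb$quad$nodes, M - 1)
    J <- crossprod(PhiQ * wq, eb$B)                       # KG x Kb
    Rm[[p]] <- crossprod(eb$Bm * sqrt(wq))                # int D^m B D^m B'
    L <- eb$quad$L
    supp <- matrix(0L, ord, L)
    Varr <- array(0, c(ord, ord, L))
    for (j in seq_len(L)) {
      rows <- which(eb$quad$interval == j)
      cols <- j:(j + ord - 1L)                             # local support
      supp[, j] <- cols
      Bj <- eb$B[rows, cols, drop = FALSE]
      Varr[, , j] <- crossprod(Bj * sqrt(wq[rows]))
    }
    # per-coefficient support norms: the fSCAD group of coefficient l is
    # int beta^2 over the support of B_l, so the penalty's nulling granularity
    # coincides with the coefficient count used by the df adjustment
    cover <- lapply(seq_len(eb$Kb), function(l)
      which(colSums(supp == l) > 0L))
    Vgrp <- vector("list", eb$Kb)
    Igrp <- vector("list", eb$Kb)
    for (l in seq_len(eb$Kb)) {
      js <- cover[[l]]
      idx <- sort(unique(as.integer(supp[, js])))
      Vl <- matrix(0, length(idx), length(idx))
      for (j in js) {
        loc <- match(supp[, j], idx)
        Vl[loc, loc] <- Vl[loc, loc] + Varr[, , j]
      }
      Vgrp[[l]] <- Vl
      Igrp[[l]] <- idx
    }
    Vsub[[p]] <- list(supp = supp, V = Varr, L = L, cover = cover,
                      Vgrp = Vgrp, Igrp = Igrp)
    blocks[[p]] <- D %*% J                                 # n x Kb
  }
  colIdx <- split(seq_len(sum(Kbs)), rep(seq_len(P), Kbs))
  U <- do.call(cbind, blocks)
  um <- colMeans(U)
  Uc <- sweep(U, 2L, um)
  # one scalar per region: unit average column variance before penalization,
  # so all regions sit on a common scale and effect shapes are preserved
  sreg <- rep(1, P)
  if (config@standardize) {
    for (p in seq_len(P)) {
      ii <- colIdx[[p]]
      sreg[p] <- sqrt(mean(colMeans(Uc[, ii, drop = FALSE]^2)))
      if (sreg[p] <= 0) sreg[p] <- 1
      Uc[, ii] <- Uc[, ii] / sreg[p]
      um[ii] <- um[ii] / sreg[p]
    }
  }
  yc <- y - mean(y)
  list(P = P, n = n, ids = regionIds(dataset), gamma = gamma, lam = lam,
       scadA = config@scadA, nullTol = config@nullTol, Ms = Ms,
       scadScale = Ms / pmax(Ms - 1, 1), Kbs = Kbs, ord = as.numeric(ord),
       scadGroups = config@scadGroups, sreg = sreg,
       colIdx = colIdx, Rm = Rm, Vsub = Vsub, Uc = Uc, um = um,
       ybar = mean(y), yc = yc, yy = sum(yc^2),
       A = crossprod(Uc) / n, g = drop(crossprod(Uc, yc)) / n,
       maxIter = config@maxIter, tol = config@tol, sseRefit = config@sseRefit)
}

# Projection RSS (and solution) for an unpenalized subset fit, robust to the
# rank deficiency induced by the Fourier stage (rank(U_p) <= KG < Kb).
projectionFit <- function(prob, cols) {
  if (!length(cols)) return(list(c = numeric(0), rss = prob$yy))
  Cs <- prob$A[cols, cols, drop = FALSE] * prob$n
  cys <- prob$g[cols] * prob$n
  R <- suppressWarnings(chol(Cs, pivot = TRUE))
  piv <- attr(R, "pivot")
  dR <- abs(diag(R))
  rank <- attr(R, "rank")
  while (rank > 0L && dR[rank] <= max(dR) * 1e-9) rank <- rank - 1L
  cc <- numeric(length(cols))
  if (rank > 0L) {
    Ru <- R[seq_len(rank), seq_len(rank), drop = FALSE]
    u <- forwardsolve(t(Ru), cys[piv[seq_len(rank)]])
    cc[piv[seq_len(rank)]] <- backsolve(Ru, u)
  }
  rss <- sum((prob$yc - prob$Uc[, cols, drop = FALSE] %*% cc)^2)
  list(c = cc, rss = rss)
}

# Full SLoS objective at a coefficient vector (for monotonicity diagnostics).
slosObjective <- function(prob, cvec, regionSet) {
  rss <- sum((prob$yc - prob$Uc %*% cvec)^2)
  pen <- 0
  for (p in regionSet) {
    cp <- cvec[prob$colIdx[[p]]]
    pen <- pen + prob$gamma[p] * drop(crossprod(cp, prob$Rm[[p]] %*% cp))
    if (prob$lam[p] > 0) {
      if (prob$scadGroups == "support") {
        u <- coefGroupRMS(prob, p, cp)
        # 1/ord: each subinterval is covered by ord coefficient groups
        pen <- pen + sum(scadPenalty(u, prob$lam[p], prob$scadA)) / prob$ord
      } else {
        u <- subintervalRMS(prob, p, cp)
        pen <- pen + sum(scadPenalty(u, prob$lam[p], prob$scadA))
      }
    }
  }
  rss / prob$n + pen
}

# fSCAD arguments u_j = sqrt((M/T) * int_{I_j} beta^2), one per knot
# subinterval; with T = M - 1 the factor M/T is scadScale.
subintervalRMS <- function(prob, p, cp) {
  vs <- prob$Vsub[[p]]
  q <- vapply(seq_len(vs$L), function(j) {
    cl <- cp[vs$supp[, j]]
    drop(crossprod(cl, vs$V[, , j] %*% cl))
  }, numeric(1))
  sqrt(pmax(prob$scadScale[p] * q, 0))
}

# fSCAD arguments u_l = sqrt((M/T) * int_{supp(B_l)} beta^2), one per effect
# coefficient; with T = M - 1 the factor M/T is scadScale.
coefGroupRMS <- function(prob, p, cp) {
  vs <- prob$Vsub[[p]]
  q <- vapply(seq_along(vs$Vgrp), function(l) {
    cl <- cp[vs$Igrp[[l]]]
    drop(crossprod(cl, vs$Vgrp[[l]] %*% cl))
  }, numeric(1))
  sqrt(pmax(prob$scadScale[p] * q, 0))
}

# LQA solver on a region subset. `frozen` is a logical over all columns;
# frozen coefficients are exact zeros excluded from the system. Freezing only
# grows. Returns the coefficient vector over all columns (zeros outside the
# region set / frozen), masks, rss and the loss path.
slosSolve <- function(prob, regionSet, init = NULL, frozenInit = NULL) {
  K <- nrow(prob$A)
  inSet <- rep(FALSE, K)
  for (p in regionSet) inSet[prob$colIdx[[p]]] <- TRUE
  frozen <- if (is.null(frozenInit)) rep(FALSE, K) else frozenInit
  frozen[!inSet] <- TRUE
  Gam <- matrix(0, K, K)
  for (p in regionSet) {
    ii <- prob$colIdx[[p]]
    Gam[ii, ii] <- prob$gamma[p] * prob$Rm[[p]]
  }
  noScad <- all(prob$lam[regionSet] == 0)
  solveActive <- function(Pen) {
    act <- which(!frozen)
    cc <- numeric(K)
    if (!length(act)) return(cc)
    S <- prob$A[act, act, drop = FALSE] + Pen[act, act, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      if (max(Pen) == 0) return({cc[act] <- projectionFit(prob, act)$c; cc})
      ch <- chol(S + diag(1e-10 * mean(diag(S)), length(act)))
    }
    cc[act] <- backsolve(ch, forwardsolve(ch, prob$g[act],
                                          upper.tri = TRUE, transpose = TRUE))
    cc
  }
  cvec <- if (is.null(init)) solveActive(Gam) else init
  cvec[frozen] <- 0
  lossPath <- slosObjective(prob, cvec, regionSet)
  iter <- 0L; converged <- FALSE
  if (noScad) {
    converged <- TRUE
  } else {
    repeat {
      iter <- iter + 1L
      W <- matrix(0, K, K)
      for (p in regionSet) {
        if (prob$lam[p] == 0) next
        ii <- prob$colIdx[[p]]
        cp <- cvec[ii]
        vs <- prob$Vsub[[p]]
        # u floored at the freeze threshold: keeps the surrogate a proper
        # majorizer while the weight stays finite until freezing removes the
        # coefficients outright
        uFloor <- prob$nullTol * prob$lam[p]
        if (prob$scadGroups == "support") {
          u <- coefGroupRMS(prob, p, cp)
          frozen[ii[u < uFloor]] <- TRUE
          wl <- prob$scadScale[p] *
            scadDerivative(pmax(u, uFloor), prob$lam[p], prob$scadA) /
            (2 * pmax(u, uFloor)) / prob$ord
          for (l in seq_along(ii)) {
            if (wl[l] == 0) next
            jj <- ii[vs$Igrp[[l]]]
            keep <- !frozen[jj]
            if (!any(keep)) next
            W[jj[keep], jj[keep]] <- W[jj[keep], jj[keep]] +
              wl[l] * vs$Vgrp[[l]][keep, keep, drop = FALSE]
          }
        } else {
          u <- subintervalRMS(prob, p, cp)
          nullSub <- u < uFloor
          # a coefficient is frozen once every subinterval in its support
          # has collapsed
          for (l in seq_along(ii)) {
            if (frozen[ii[l]]) next
            if (all(nullSub[vs$cover[[l]]])) frozen[ii[l]] <- TRUE
          }
          wj <- prob$scadScale[p] *
            scadDerivative(pmax(u, uFloor), prob$lam[p], prob$scadA) /
            (2 * pmax(u, uFloor))
          for (j in seq_len(vs$L)) {
            if (wj[j] == 0) next
            jj <- ii[vs$supp[, j]]
            keep <- !frozen[jj]
            if (!any(keep)) next
            W[jj[keep], jj[keep]] <- W[jj[keep], jj[keep]] +
              wj[j] * vs$V[keep, keep, j]
          }
        }
      }
      cOld <- cvec
      cvec <- solveActive(Gam + W)
      lossPath <- c(lossPath, slosObjective(prob, cvec, regionSet))
      delta <- max(abs(cvec - cOld)) / max(1, max(abs(cOld)))
      if (delta < prob$tol) { converged <- TRUE; break }
      if (iter >= prob$maxIter) break
    }
    # final freeze pass so masks reflect the returned coefficients
    for (p in regionSet) {
      if (prob$lam[p] == 0) next
      ii <- prob$colIdx[[p]]
      uFloor <- prob$nullTol * prob$lam[p]
      if (prob$scadGroups == "support") {
        u <- coefGroupRMS(prob, p, cvec[ii])
        frozen[ii[u < uFloor]] <- TRUE
      } else {
        u <- subintervalRMS(prob, p, cvec[ii])
        nullSub <- u < uFloor
        vs <- prob$Vsub[[p]]
        for (l in seq_along(ii)) {
          if (frozen[ii[l]]) next
          if (all(nullSub[vs$cover[[l]]])) frozen[ii[l]] <- TRUE
        }
      }
    }
    cvec[frozen] <- 0
  }
  rss <- sum((prob$yc - prob$Uc %*% cvec)^2)
  list(c = cvec, frozen = frozen, rss = rss, nIter = iter,
       converged = converged, lossPath = lossPath)
}

#' Fit the multi-region locally sparse functional regression
#'
#' Minimizes the penalized least-squares loss combining squared trait
#' residuals, per-region roughness penalties `gamma_p ||D^m beta_p||^2`, and
#' per-region fSCAD sparsity penalties that compress effect functions (or
#' subintervals of them) exactly to zero. Genotype functions come from the
#' Fourier smoothing layer; effect functions are order-4 B-splines with knots
#' at the region's equispaced marker grid. The fSCAD term is evaluated per
#' knot subinterval through the SCAD function of the local root-mean-square
#' of `beta_p` and minimized by local quadratic approximation, each iteration
#' a generalized ridge solve. With `lam = 0` and `gamma = 0` the fit reduces
#' to unpenalized functional least squares.
#'
#' With a [LocusWeightScheme] supplied, genotype columns are Beta-density
#' weighted before smoothing, giving the LW-SLoS variant; per-region
#' `gamma`/`lam` vectors (e.g. from [wslosConfig]) give W-SLoS.
#'
#' @param dataset a [MultiRegionDataset] with trait attached.
#' @param K number of Fourier basis functions for the genotype stage.
#' @param config a [SLoSConfig-class] (see [slosConfig]).
#' @param lambda_x genotype smoothing penalty.
#' @param weights optional [LocusWeightScheme] for locus weighting.
#' @return a [SLoSFit-class]; the fitting state needed by
#'   [adjustedPartialF] travels with the object.
#' @examples
#' d <- simulateStudy(simulationDesign("common25", n = 150,
#'                    snpsPerRegion = 10, assocRegions = 1:2), seed = 7)
#' fit <- fitMultiSLoS(d$dataset, K = 7, config = slosConfig(0.1, 0.1))
#' sum(!nullRegions(fit))
#' @export
fitMultiSLoS <- function(dataset, K = 25L, config = slosConfig(),
                         lambda_x = 0, weights = NULL) {
  prob <- buildSLoSProblem(dataset, K, config, lambda_x, weights)
  sol <- slosSolve(prob, seq_len(prob$P))
  fit <- wrapSLoSFit(prob, sol)
  attr(fit, "problem") <- prob
  attr(fit, "solution") <- sol
  fit
}

wrapSLoSFit <- function(prob, sol) {
  # back-transform to natural effect-function units
  coefs <- lapply(seq_len(prob$P), function(p)
    sol$c[prob$colIdx[[p]]] / prob$sreg[p])
  masks <- lapply(prob$colIdx, function(ii) sol$frozen[ii])
  mu0 <- prob$ybar - sum(prob$um * sol$c)
  new("SLoSFit", mu0 = mu0, coef = coefs, nullCoefMask = masks,
      nullRegionMask = vapply(masks, all, logical(1)), rss = sol$rss,
      nIter = sol$nIter, converged = sol$converged, regionIds = prob$ids)
}

#' @describeIn fitMultiSLoS Logical vector: which regions were compressed to
#'   a fully null effect function.
#' @param fit a [SLoSFit-class].
#' @export
nullRegions <- function(fit) {
  stats::setNames(fit@nullRegionMask, fit@regionIds)
}

#' Count of non-null effect coefficients in one region
#'
#' The number of B-spline coefficients of the region's effect function that
#' were not compressed to null; this is the numerator degrees of freedom of
#' the adjusted partial F test.
#'
#' @param fit a [SLoSFit-class].
#' @param region region index or id.
#' @return integer count.
#' @export
countNonnullCoefficients <- function(fit, region) {
  if (is.character(region)) region <- match(region, fit@regionIds)
  sum(!fit@nullCoefMask[[region]])
}

#' Degrees-of-freedom-adjusted partial F test after SLoS compression
#'
#' Nested-model F test for one non-null region, with degrees of freedom that
#' count only coefficients not compressed to null: the full model refits all
#' non-null regions (`SSE(full)`), the reduced model excludes the tested
#' region (`SSE(reduced)`), the numerator df is the tested region's non-null
#' coefficient count and the denominator df is
#' `n - (total non-null coefficients over non-null regions) - 1`. Refits use
#' the penalized estimator restricted to the stated region set by default
#' (`sseRefit = "penalized"` in the config), or plain least squares with
#' `sseRefit = "ols"`. Regions whose effect was fully compressed are reported
#' with `selected = FALSE` and `p_value = 1`.
#'
#' @param fit a [SLoSFit-class] from [fitMultiSLoS].
#' @param region region index or id.
#' @return one-row data.frame (`region_id`, `selected`, `F`, `df1`, `df2`,
#'   `p_value`).
#' @export
adjustedPartialF <- function(fit, region) {
  prob <- attr(fit, "problem")
  sol <- attr(fit, "solution")
  if (is.null(prob)) stop("fit does not carry its fitting state")
  if (is.character(region)) region <- match(region, fit@regionIds)
  if (fit@nullRegionMask[region])
    return(data.frame(region_id = fit@regionIds[region], selected = FALSE,
                      F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                      p_value = 1, stringsAsFactors = FALSE))
  B <- which(!fit@nullRegionMask)
  kCounts <- vapply(seq_len(prob$P), function(p) sum(!sol$frozen[
    prob$colIdx[[p]]]), integer(1))
  dfFull <- prob$n - sum(kCounts[B]) - 1L
  if (dfFull <= 0) stop("no residual degrees of freedom after adjustment")
  dfRed <- kCounts[region]
  if (prob$sseRefit == "penalized") {
    sseFull <- sol$rss
    red <- slosSolve(prob, setdiff(B, region), init = sol$c,
                     frozenInit = sol$frozen)
    sseRed <- red$rss
  } else {
    actCols <- function(set) {
      ii <- unlist(prob$colIdx[set], use.names = FALSE)
      ii[!sol$frozen[ii]]
    }
    sseFull <- projectionFit(prob, actCols(B))$rss
    sseRed <- projectionFit(prob, actCols(setdiff(B, region)))$rss
  }
  Fstat <- max(((sseRed - sseFull) / dfRed) / (sseFull / dfFull), 0)
  data.frame(region_id = fit@regionIds[region], selected = TRUE, F = Fstat,
             df1 = dfRed, df2 = dfFull,
             p_value = pf(Fstat, dfRed, dfFull, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Multi-SLoS / W-SLoS / LW-SLoS association test over all regions
#'
#' Fits the locally sparse multi-region functional regression and applies the
#' degrees-of-freedom-adjusted partial F test to every region. Regions
#' compressed to a fully null effect function are returned unselected with
#' `p_value = 1`.
#'
#' @inheritParams fitMultiSLoS
#' @return data.frame with one row per region.
#' @export
slosTest <- function(dataset, K = 25L, config = slosConfig(),
                     lambda_x = 0, weights = NULL) {
  fit <- fitMultiSLoS(dataset, K = K, config = config, lambda_x = lambda_x,
                      weights = weights)
  res <- do.call(rbind, lapply(seq_along(fit@coef), function(p)
    adjustedPartialF(fit, p)))
  rownames(res) <- NULL
  res
}

#' @describeIn slosTest Single-region SLoS baseline: each region is fitted
#'   and tested on its own (P = 1), the single-gene-region comparator for the
#'   multi-region methods.
#' @export
singleRegionSLoSTest <- function(dataset, K = 25L, config = slosConfig(),
                                 lambda_x = 0, weights = NULL) {
  res <- do.call(rbind, lapply(seq_len(nRegions(dataset)), function(p) {
    one <- multiRegionDataset(dataset@regions[p], dataset@y)
    cfg <- slosConfig(gamma = rep_len(config@gamma, nRegions(dataset))[p],
                      lam = rep_len(config@lam, nRegions(dataset))[p],
                      scadA = config@scadA, splineOrder = config@splineOrder,
                      m = config@m, maxIter = config@maxIter,
                      tol = config@tol, nullTol = config@nullTol,
                      sseRefit = config@sseRefit)
    slosTest(one, K = K, config = cfg, lambda_x = lambda_x,
             weights = weights)
  }))
  rownames(res) <- NULL
  res
}
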