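# Fourier smoothing layer: basis evaluation, closed-form roughness penalties,
# penalized least-squares expansion of genotype rows, basis cross-products.

#' Evaluate an orthonormal Fourier basis
#'
#' Returns the `M x K` matrix of the first `K` orthonormal Fourier basis
#' functions on `[0, T]` evaluated at `points`. Column 1 is the constant
#' `1/sqrt(T)`; columns then alternate `sqrt(2/T) sin(2 pi k t/T)` and
#' `sqrt(2/T) cos(2 pi k t/T)` for k = 1, 2, .... The system is exactly
#' orthonormal under the continuous inner product `integral_0^T f g dt`.
#'
#' @param K number of basis functions (>= 1).
#' @param points evaluation positions, all within `[0, T]`.
#' @param T domain length (default 1).
#' @return numeric matrix, `length(points) x K`.
#' @examples
#' evalFourierBasis(3, c(0, 0.25, 0.5))
#' @export
evalFourierBasis <- function(K, points, T = 1) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (any(points < 0) || any(points > T))
    stop("evaluation points must lie within [0, T]")
  Phi <- matrix(0, length(points), K)
  Phi[, 1L] <- 1 / sqrt(T)
  if (K > 1L) {
    amp <- sqrt(2 / T)
    for (col in 2:K) {
      k <- (col %/% 2L)
      w <- 2 * pi * k / T
      Phi[, col] <- if (col %% 2L == 0L) amp * sin(w * points)
                    else amp * cos(w * points)
    }
  }
  Phi
}

#' @describeIn evalFourierBasis Evaluate the basis of a [FourierBasis] object
#'   at its own grid (or at `at` if given).
#' @param basis a [FourierBasis].
#' @param at optional alternative evaluation points.
#' @export
basisMatrix <- function(basis, at = NULL) {
  pts <- if (is.null(at)) basis@evalPoints else at
  evalFourierBasis(basis@K, pts, basis@T)
}

#' Roughness penalty matrix of a Fourier basis
#'
#' Closed-form `K x K` matrix of inner products of m-th derivatives,
#' `[R]_{jk} = integral_0^T D^m phi_j D^m phi_k dt`. For the orthonormal
#' Fourier system the matrix is diagonal: 0 for the constant function and
#' `omega^(2m)` with `omega = 2 pi k / T` for both members of the k-th
#' sine/cosine pair.
#'
#' @param basis a [FourierBasis].
#' @param m derivative order (>= 1, default 2).
#' @return list with elements `R2` (the matrix) and `m`.
#' @export
roughnessMatrix <- function(basis, m = 2L) {
  m <- as.integer(m)
  if (m < 1L) stop("derivative order m must be >= 1")
  K <- basis@K
  d <- numeric(K)
  if (K > 1L) {
    for (col in 2:K) {
      k <- col %/% 2L
      d[col] <- (2 * pi * k / basis@T)^(2 * m)
    }
  }
  list(R2 = diag(d, nrow = K), m = m)
}

#' Penalized Fourier expansion of genotype rows
#'
#' Expands each row of an `n x M` genotype matrix on the Fourier basis by
#' penalized least squares: the coefficient row for individual i solves
#' `min ||X_i' - Phi d||^2 + lambda_x d' R2 d`, giving
#' `d_i = (Phi'Phi + lambda_x R2)^{-1} Phi' X_i'`. With `lambda_x = 0` and
#' `K = M` this interpolates the data exactly.
#'
#' When `lambda_x = 0` and the normal equations are singular (e.g. more basis
#' functions than markers), a small automatic ridge
#' `lambda_x = 1e-8 trace(Phi'Phi)/K` is substituted with a message.
#'
#' @param X `n x M` genotype matrix (rows = individuals).
#' @param basis a [FourierBasis] whose `evalPoints` match the M markers.
#' @param lambda_x roughness penalty weight (>= 0).
#' @return list with `d` (`n x K` coefficient matrix), `lambda_x` actually
#'   used, and `basis`.
#' @examples
#' b <- fourierBasis(K = 5, M = 12)
#' sm <- smoothGenotypeRegion(matrix(rbinom(60, 2, 0.3), 5, 12), b)
#' dim(sm$d)
#' @export
smoothGenotypeRegion <- function(X, basis, lambda_x = 0) {
  X <- as.matrix(X)
  if (ncol(X) != length(basis@evalPoints))
    stop("ncol(X) must match the basis evaluation grid")
  if (lambda_x < 0) stop("lambda_x must be >= 0")
  Phi <- basisMatrix(basis)
  PtP <- crossprod(Phi)
  R2 <- roughnessMatrix(basis, 2L)$R2
  A <- PtP + lambda_x * R2
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    if (lambda_x > 0)
      stop("singular smoothing system despite positive lambda_x")
    lambda_x <- 1e-8 * sum(diag(PtP)) / basis@K
    message("singular normal equations at lambda_x = 0; ",
            "using ridge fallback lambda_x = ", signif(lambda_x, 3))
    ch <- chol(PtP + lambda_x * R2)
  }
  d <- t(backsolve(ch, forwardsolve(ch, crossprod(Phi, t(X)),
                                    upper.tri = TRUE, transpose = TRUE)))
  list(d = d, lambda_x = lambda_x, basis = basis)
}

#' Cross-product matrix of two Fourier systems
#'
#' `KG x Kb` matrix of inner products `integral phi_k varphi_k' dt` between a
#' genotype basis and an effect basis on the same domain. For two orthonormal
#' Fourier systems of the same family this is the truncated identity, which
#' is what lets the functional regression collapse onto the raw coefficient
#' blocks.
#'
#' @param genotypeBasis,effectBasis [FourierBasis] objects on the same `[0,T]`.
#' @return numeric matrix `KG x Kb`.
#' @export
crossProductMatrix <- function(genotypeBasis, effectBasis) {
  if (!isTRUE(all.equal(genotypeBasis@T, effectBasis@T)))
    stop("bases must share the same domain [0, T]")
  KG <- genotypeBasis@K
  Kb <- effectBasis@K
  J <- matrix(0, KG, Kb)
  diag(J) <- 1
  J
}

# Gauss-Legendre nodes/weights on [a, b]; used for all B-spline quadrature.
# 4-point rule is exact through degree 7, enough for products of cubics.
gaussLegendre4 <- function(a, b) {
  x <- c(-0.8611363115940526, -0.3399810435848563,
         0.3399810435848563, 0.8611363115940526)
  w <- c(0.3478548451374538, 0.6521451548625461,
         0.6521451548625461, 0.3478548451374538)
  h <- (b - a) / 2
  list(x = (a + b) / 2 + h * x, w = h * w)
}

# Quadrature grid over the subintervals of a knot sequence: nodes, weights,
# and the subinterval index of each node.
subintervalQuadrature <- function(knots) {
  L <- length(knots) - 1L
  nodes <- numeric(4L * L); wts <- numeric(4L * L); idx <- integer(4L * L)
  for (j in seq_len(L)) {
    g <- gaussLegendre4(knots[j], knots[j + 1L])
    r <- (4L * (j - 1L) + 1L):(4L * j)
    nodes[r] <- g$x; wts[r] <- g$w; idx[r] <- j
  }
  list(nodes = nodes, weights = wts, interval = idx, L = L)
}
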