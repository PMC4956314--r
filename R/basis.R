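#' Orthonormal basis on a season grid
#'
#' Evaluates K basis functions on the grid nodes, orthonormal under the
#' quadrature inner product the score stage uses: the left Riemann sum
#' \code{<f, g> = sum_{m=0}^{M-1} f(t_m) g(t_m) dt} (the final node is
#' dropped, matching the score convention). The Fourier family is exactly
#' orthonormal under this sum by discrete trigonometric orthogonality; the
#' cubic B-spline family is orthonormalized by Gram-Schmidt in the same
#' inner product.
#'
#' @param family \code{"fourier"} (constant then sin/cos pairs of increasing
#'   frequency) or \code{"bspline"} (cubic B-splines, orthonormalized).
#' @param K Number of basis functions, \code{1 <= K <= grid$M}.
#' @param grid A [season_grid()].
#' @return Object of class \code{"basis_spec"}: \code{family}, \code{K},
#'   \code{values} (\code{(M+1) x K} matrix of \code{phi_k(t_m)}),
#'   \code{grid}.
#' @examples
#' b <- make_basis("fourier", 3, season_grid(2000))
#' round(basis_gram(b), 10)   # identity
#' @export
make_basis <- function(family = c("fourier", "bspline"), K, grid) {
  family <- match.arg(family)
  if (K < 1 || K > grid$M)
    stop("K must satisfy 1 <= K <= M = ", grid$M)
  t <- grid$t
  Tlen <- grid$T
  if (family == "fourier") {
    V <- matrix(NA_real_, length(t), K)
    V[, 1] <- 1 / sqrt(Tlen)
    if (K > 1) for (k in 2:K) {
      p <- k %/% 2
      w <- 2 * pi * p * t / Tlen
      V[, k] <- sqrt(2 / Tlen) * if (k %% 2 == 0) sin(w) else cos(w)
    }
  } else {
    degree <- min(3L, K - 1L)
    B <- splines::bs(t, df = K, degree = degree, intercept = TRUE)
    class(B) <- "matrix"
    # Gram-Schmidt under the left-sum inner product via QR of the
    # weighted design restricted to nodes 0..M-1
    M <- grid$M
    qrd <- qr(B[seq_len(M), , drop = FALSE] * sqrt(grid$dt))
    Rm <- qr.R(qrd)
    if (any(abs(diag(Rm)) < 1e-10)) stop("B-spline basis is rank deficient")
    V <- t(backsolve(Rm, t(B), transpose = TRUE))
    V <- sweep(V, 2, sign(diag(Rm)), "*")
  }
  colnames(V) <- paste0("phi", seq_len(K))
  structure(list(family = family, K = K, values = V, grid = grid),
            class = "basis_spec")
}

#' Quadrature Gram matrix of a basis
#'
#' \code{G_kl = sum_{m=0}^{M-1} phi_k(t_m) phi_l(t_m) dt}; identity (to
#' quadrature accuracy) for a [make_basis()] object.
#' @param basis A \code{basis_spec}.
#' @return K x K matrix.
#' @export
basis_gram <- function(basis) {
  M <- basis$grid$M
  crossprod(basis$values[seq_len(M), , drop = FALSE]) * basis$grid$dt
}

#' Quadrature scores of curves against a basis
#'
#' Left-Riemann quadrature of each curve row against every basis function:
#' the building block of the score matrix.
#' @param X \code{n_curves x (M+1)} matrix of curve values on the grid.
#' @param basis A [make_basis()].
#' @return \code{n_curves x K} score matrix.
#' @export
quadrature_scores <- function(X, basis) {
  M <- basis$grid$M
  if (ncol(X) != M + 1L)
    stop("curve/grid mismatch: curves have ", ncol(X), " nodes, grid has ",
         M + 1L)
  X[, seq_len(M), drop = FALSE] %*%
    basis$values[seq_len(M), , drop = FALSE] * basis$grid$dt
}

#' Score matrix of a lagged design
#'
#' Evaluates every design-matrix entry of the reduced scalar-on-function
#' model: \code{Z[i, (j,k)] = sum_{m=0}^{M-1} phi_k(t_m) X_ij(t_m) dt},
#' the numeric integral of basis function k against season i's reconstructed
#' discharge curve for stream j. Columns are stream-major
#' (\code{"<stream>:phi<k>"}).
#'
#' @param design A [build_lagged_design()] object.
#' @param basis A [make_basis()] on the same grid as the latent curves.
#' @param covariate_scale \code{"log"} uses the posterior-mean log-discharge
#'   curve DR(t) directly; \code{"linear"} back-transforms to
#'   \code{exp(DR) - zeta}.
#' @return List with \code{Z} (n x J*K matrix), \code{y} (response vector),
#'   \code{streams}, \code{seasons}, \code{K}.
#' @export
compute_scores <- function(design, basis,
                           covariate_scale = c("log", "linear")) {
  covariate_scale <- match.arg(covariate_scale)
  streams <- attr(design, "streams")
  n <- length(design)
  K <- basis$K
  Z <- matrix(NA_real_, n, length(streams) * K)
  colnames(Z) <- as.vector(outer(paste0("phi", seq_len(K)),
                                 streams,
                                 function(k, s) paste(s, k, sep = ":")))
  for (i in seq_len(n)) for (j in seq_along(streams)) {
    lat <- design[[i]]$covariates[[streams[j]]]
    x <- lat$mean
    if (length(x) != basis$grid$M + 1L)
      stop("latent curve for ", streams[j], " season ", lat$season_label,
           " does not share the basis grid")
    if (covariate_scale == "linear") x <- exp(x) - lat$zeta
    Z[i, (j - 1L) * K + seq_len(K)] <-
      quadrature_scores(matrix(x, 1), basis)
  }
  list(Z = Z,
       y = vapply(design, function(r) r$response$y, numeric(1)),
       streams = streams,
       seasons = vapply(design, function(r) r$response$season_label,
                        integer(1)),
       K = K)
}
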