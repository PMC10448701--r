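#' Cayley-Menger matrix of a point set
#'
#' Builds the bordered matrix of squared pairwise distances whose determinant
#' encodes the squared content of the simplex spanned by the points. For k
#' points the matrix is (k+1) x (k+1): the first row and column are
#' \code{c(0, 1, ..., 1)} and the remaining block holds the squared distances.
#'
#' @param d square symmetric matrix of pairwise distances among k points
#'   (zero diagonal, nonnegative entries). A single point may be given as a
#'   1 x 1 zero matrix.
#' @return a numeric (k+1) x (k+1) symmetric matrix.
#' @seealso [simplex_volume()], [apex_height()]
#' @examples
#' cayley_menger_matrix(matrix(c(0, 2, 2, 0), 2))
#' @export
cayley_menger_matrix <- function(d) {
  d <- as.matrix(d)
  check_distance_block(d)
  k <- nrow(d)
  cm <- matrix(1, k + 1L, k + 1L)
  cm[1L, 1L] <- 0
  cm[-1L, -1L] <- d^2
  cm
}

#' Simplex volume from pairwise distances
#'
#' Computes the (k-1)-dimensional content of the simplex on k vertices from
#' their pairwise distances alone, via the Cayley-Menger determinant:
#' \deqn{V_{k-1} = \sqrt{ |\det CM| / (2^{k-1} ((k-1)!)^2) }.}
#' The determinant is evaluated in sign-and-log form so large simplices do
#' not overflow, and its absolute value is used, which shields the result
#' against sign flips caused by round-off or mildly non-Euclidean inputs.
#' A single point has content 1 by convention (the empty product).
#'
#' @inheritParams cayley_menger_matrix
#' @param log logical; return the natural log of the volume instead
#'   (\code{-Inf} for a degenerate simplex).
#' @return nonnegative numeric scalar (or its log).
#' @examples
#' simplex_volume(matrix(c(0, 2, 2, 0), 2))        # a segment of length 2
#' d <- matrix(1, 3, 3); diag(d) <- 0
#' simplex_volume(d)                               # sqrt(3)/4, unit triangle
#' @export
simplex_volume <- function(d, log = FALSE) {
  d <- as.matrix(d)
  check_distance_block(d)
  k <- nrow(d)
  n <- k - 1L # simplex dimension
  ld <- determinant(cayley_menger_matrix(d), logarithm = TRUE)
  log_v <- 0.5 * (as.numeric(ld$modulus) - n * log(2) - 2 * lgamma(n + 1))
  if (log) log_v else exp(log_v)
}

#' Height of an apex over a simplex base
#'
#' Distance from an extra point (the apex) to the affine hull of m base
#' points, computed from distances only through the volume ratio
#' \deqn{h = m \, V_m / V_{m-1},} where \eqn{V_m} is the content of the
#' (m+1)-vertex simplex including the apex and \eqn{V_{m-1}} that of the
#' base. When the base is degenerate -- its Cayley-Menger matrix is
#' rank-deficient, i.e. the smallest QR pivot falls below \code{tol} times
#' the largest matrix entry -- the ratio is meaningless and \code{NA} is
#' returned so that callers can resample.
#'
#' @param base square symmetric matrix of pairwise distances among the m
#'   base points.
#' @param apex_dists numeric vector of length m, distances from the apex to
#'   each base point.
#' @param tol relative pivot tolerance declaring the base degenerate.
#' @return nonnegative numeric scalar, or \code{NA_real_} for a degenerate
#'   base.
#' @examples
#' d <- matrix(1, 2, 2); diag(d) <- 0
#' apex_height(d, c(1, 1)) # altitude of the unit equilateral triangle
#' @export
apex_height <- function(base, apex_dists, tol = 1e-12) {
  base <- as.matrix(base)
  check_distance_block(base)
  m <- nrow(base)
  apex_dists <- as.numeric(apex_dists)
  if (length(apex_dists) != m) {
    stop("'apex_dists' must have one distance per base point")
  }
  if (anyNA(apex_dists) || any(apex_dists < 0)) {
    stop("apex distances must be nonnegative and finite")
  }
  full <- rbind(cbind(base, apex_dists), c(apex_dists, 0))
  if (max(full) == 0) return(0)
  if (m > 1) {
    cm <- cayley_menger_matrix(base)
    piv <- abs(diag(qr(cm)$qr))
    if (min(piv) < tol * max(abs(cm))) return(NA_real_)
  }
  log_vf <- simplex_volume(full, log = TRUE)
  log_vb <- simplex_volume(base, log = TRUE)
  exp(log(m) + log_vf - log_vb)
}

# shared validation for distance blocks fed to the geometry layer
check_distance_block <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 1L) {
    stop("expected a square matrix with at least one point")
  }
  if (anyNA(d) || any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (any(abs(d - t(d)) > 1e-8 * max(1, max(abs(d))))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  invisible(d)
}
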