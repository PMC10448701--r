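#' Classical (Torgerson) metric MDS embedding
#'
#' Embeds a distance matrix in Euclidean space by double-centering the
#' squared distances, eigendecomposing, and keeping the leading nonnegative
#' eigenpairs. Deterministic and exact for Euclidean-embeddable input.
#' Negative eigenvalues (non-Euclidean input) are clipped to zero and
#' counted. When \code{target_dim} is \code{NULL} the embedding dimension is
#' the number of eigenvalues exceeding \code{tol} times the largest one,
#' i.e. the affine rank of the configuration.
#'
#' @param D symmetric distance matrix (or \code{dist} object).
#' @param target_dim embedding dimension, or \code{NULL} to use the rank.
#' @param tol relative eigenvalue tolerance defining the rank.
#' @return list of class \code{"orthomds_embedding"} with \code{coords}
#'   (N x d), \code{eig} (all eigenvalues), \code{n_clipped} (count of
#'   negative eigenvalues) and \code{source = "mds"}.
#' @export
mds_embed <- function(D, target_dim = NULL, tol = 1e-9) {
  D <- as_distance_matrix(D)
  N <- nrow(D)
  if (!is.null(target_dim) && target_dim > N - 1L) {
    stop("'target_dim' cannot exceed N - 1")
  }
  B <- -0.5 * scale(t(scale(t(D^2), scale = FALSE)), scale = FALSE)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (max(e$values) <= 0) {
    stop("no positive eigenvalue: the input cannot be embedded")
  }
  rank <- sum(e$values > tol * max(e$values))
  d <- if (is.null(target_dim)) rank else as.integer(target_dim)
  lam <- pmax(e$values[seq_len(d)], 0)
  coords <- e$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam), d)
  rownames(coords) <- rownames(D)
  structure(list(coords = coords, eig = e$values, rank = rank,
                 n_clipped = sum(e$values < 0), source = "mds"),
            class = "orthomds_embedding")
}

#' Fit the main subspace through the regular points
#'
#' PCA on the coordinates of the points not flagged as outliers: the center
#' is their mean and the directions are the leading \code{ndim} principal
#' axes. Axis signs are fixed deterministically (the largest-magnitude
#' loading of each axis is made positive) so repeated runs agree exactly.
#'
#' @param coords N x d coordinate matrix.
#' @param regular indices of the regular (non-outlier) points.
#' @param ndim subspace dimension; must be smaller than the number of
#'   regular points and at most d.
#' @return list with \code{center} (length d) and \code{rotation}
#'   (d x ndim, orthonormal columns).
#' @export
fit_subspace <- function(coords, regular, ndim) {
  coords <- as.matrix(coords)
  regular <- as.integer(regular)
  if (length(regular) <= ndim) {
    stop("need more than ", ndim, " regular points to fit a ", ndim,
         "-dimensional subspace")
  }
  if (ndim > ncol(coords)) stop("'ndim' cannot exceed the ambient dimension")
  X <- coords[regular, , drop = FALSE]
  center <- colMeans(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = ndim)
  V <- pc$rotation[, seq_len(ndim), drop = FALSE]
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  list(center = center, rotation = V)
}

#' Project outliers onto a fitted subspace and recompute distances
#'
#' Each flagged point x is replaced by its orthogonal projection
#' center + V V' (x - center); all other rows are untouched. The corrected
#' distance matrix is the all-pairs Euclidean distances of the corrected
#' coordinates.
#'
#' @inheritParams fit_subspace
#' @param outliers indices of the points to project.
#' @param basis subspace basis from [fit_subspace()].
#' @return list with \code{coords} (corrected coordinates) and \code{D}
#'   (corrected distance matrix).
#' @export
project_outliers <- function(coords, outliers, basis) {
  coords <- as.matrix(coords)
  out <- coords
  if (length(outliers)) {
    V <- basis$rotation
    ctr <- basis$center
    X <- sweep(coords[outliers, , drop = FALSE], 2, ctr)
    out[outliers, ] <- sweep(X %*% V %*% t(V), 2, ctr, `+`)
  }
  list(coords = out, D = full_dist(out))
}

full_dist <- function(x) {
  D <- as.matrix(stats::dist(x))
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}
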