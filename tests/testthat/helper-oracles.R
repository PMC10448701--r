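# Independent coordinate-based oracles against which the distance-only
# geometry is checked.

# (k-1)-dimensional content of the simplex on the rows of X, via the Gram
# determinant of the edge vectors: sqrt(det(M'M)) / (k-1)!
vol_gram <- function(X) {
  X <- as.matrix(X)
  k <- nrow(X)
  if (k == 1) return(1)
  M <- t(X[-1, , drop = FALSE]) - X[1, ]
  g <- det(crossprod(M))
  sqrt(max(g, 0)) / factorial(k - 1)
}

# Euclidean distance from point x to the affine hull of the rows of B,
# via least squares on the edge vectors.
dist_to_hull <- function(x, B) {
  B <- as.matrix(B)
  r <- x - B[1, ]
  if (nrow(B) == 1) return(sqrt(sum(r^2)))
  A <- t(B[-1, , drop = FALSE]) - B[1, ]
  fit <- qr.solve(qr(A, LAPACK = TRUE), r)
  sqrt(sum((r - A %*% fit)^2))
}

edist <- function(X) as.matrix(dist(X))
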