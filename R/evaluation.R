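#' Shepard pairs and RMSE between two distance matrices
#'
#' One (reference, test) pair per unordered point pair, plus the root mean
#' squared error over the pairs — the scalar version of a Shepard diagram.
#'
#' @param d_ref,d_test distance matrices (or \code{dist} objects) over the
#'   same points.
#' @return list with \code{pairs} (data frame with columns \code{ref} and
#'   \code{test}) and \code{rmse}.
#' @export
shepard <- function(d_ref, d_test) {
  d_ref <- as_distance_matrix(d_ref)
  d_test <- as_distance_matrix(d_test)
  if (!identical(dim(d_ref), dim(d_test))) {
    stop("distance matrices must have the same size")
  }
  up <- upper.tri(d_ref)
  pairs <- data.frame(ref = d_ref[up], test = d_test[up])
  list(pairs = pairs, rmse = sqrt(mean((pairs$ref - pairs$test)^2)))
}

#' Mean distance from outliers to the barycenter of regular points
#'
#' In the first \code{reduced_dim} embedding coordinates, the mean Euclidean
#' distance from each flagged point to the mean position of the non-flagged
#' points; a summary of how far the outliers sit from the bulk in the
#' reduced view.
#'
#' @param coords N x d coordinate matrix.
#' @param outliers nonempty index vector of flagged points.
#' @param reduced_dim number of leading coordinates to use.
#' @return nonnegative scalar.
#' @export
outlier_barycenter_distance <- function(coords, outliers,
                                        reduced_dim = ncol(coords)) {
  coords <- as.matrix(coords)
  if (!length(outliers)) stop("'outliers' must be nonempty")
  if (reduced_dim > ncol(coords)) {
    stop("'reduced_dim' cannot exceed the ambient dimension")
  }
  cols <- seq_len(reduced_dim)
  bary <- colMeans(coords[-outliers, cols, drop = FALSE])
  X <- sweep(coords[outliers, cols, drop = FALSE], 2, bary)
  mean(sqrt(rowSums(X^2)))
}

#' Dimension-bias sweep over outlier fractions
#'
#' For each outlier fraction and replicate: generate a Gaussian-subspace
#' dataset, run the detection pipeline, and record the dimension bias
#' before and after the hypergeometric correction, together with outlier
#' precision and recall against the planted outliers. Each cell carries its
#' own seed so any row can be re-run in isolation.
#'
#' @param p_values outlier fractions to sweep.
#' @param d_star true main-subspace dimension.
#' @param N points per dataset.
#' @param replicates replicates per fraction.
#' @param dims,S,c detection settings, see [orthomds()].
#' @param seed base seed; cell seeds are drawn from it.
#' @param ... further arguments to [sim_gaussian_subspace()].
#' @return data frame in long format, one row per (p, replicate).
#' @export
bias_sweep <- function(p_values, d_star = 40, N = 1000, replicates = 10,
                       dims = NULL, S = 100, c = 3, seed = 1, ...) {
  set.seed(seed)
  cells <- expand.grid(p = p_values, replicate = seq_len(replicates))
  cells$seed <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    set.seed(cells$seed[k])
    sim <- sim_gaussian_subspace(N = N, d_star = d_star, p = cells$p[k], ...)
    fit <- orthomds(sim_dist(sim), dims = dims, S = S, c = c)
    planted <- sim$outlier_idx
    hit <- length(intersect(fit$outliers, planted))
    data.frame(
      p = cells$p[k], replicate = cells$replicate[k], seed = cells$seed[k],
      d_star = d_star, N = N,
      n_raw = fit$n_raw, n_star = fit$n_star, delta = fit$delta,
      bias_before = fit$n_raw - d_star, bias_after = fit$n_star - d_star,
      precision = if (length(fit$outliers)) hit / length(fit$outliers) else NA,
      recall = if (length(planted)) hit / length(planted) else NA
    )
  })
  do.call(rbind, rows)
}
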