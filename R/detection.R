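#' Sample base points for one simplex draw
#'
#' Draws the n+1 base vertices used to test dimension n for apex point i:
#' a uniform sample without replacement from all points except i. Driven by
#' R's global RNG, so results are reproducible under [set.seed()].
#'
#' @param i apex point index (1-based).
#' @param n tested dimension; n+1 partners are drawn.
#' @param N total number of points.
#' @return integer vector of n+1 distinct indices, none equal to \code{i}.
#' @export
sample_simplex_partners <- function(i, n, N) {
  if (n + 1L > N - 1L) {
    stop("tested dimension ", n, " needs ", n + 1L,
         " partners but only ", N - 1L, " points are available")
  }
  sample((1:N)[-i], n + 1L)
}

#' Median simplex-height profile of a distance matrix
#'
#' For every point i and every tested dimension n, samples \code{S} bases of
#' n+1 other points, computes the apex height of i over each base from the
#' distances alone (see [apex_height()]), and records the median height
#' \eqn{h_i^n}. The per-dimension mean \eqn{\tilde h_n} and population
#' standard deviation \eqn{\sigma_n} of the medians drive dimension
#' estimation and outlier detection. Degenerate bases (flat simplices) are
#' resampled, with a budget of \code{max_retry} retries per draw; a point
#' that accumulates more than \code{50 * S} degenerate draws at one
#' dimension aborts with an error, since that signals a pathological input.
#'
#' @param D symmetric distance matrix (or \code{dist} object).
#' @param dims integer vector of consecutive tested dimensions.
#' @param S number of simplices sampled per point and dimension.
#' @param engine \code{"cpp"} for the compiled kernel (default) or
#'   \code{"r"} for the plain-R reference implementation.
#' @param max_retry resampling budget per draw for degenerate bases.
#' @param degen_tol relative degeneracy tolerance for base contents.
#' @return an object of class \code{"orthomds_profile"}: a list with
#'   \code{median_heights} (N x length(dims)), \code{h_mean}, \code{h_sd},
#'   \code{dims}, \code{degenerate_counts} and \code{n_negative_sq} (count
#'   of draws whose Cayley-Menger determinant had an anomalous sign).
#' @export
height_profile <- function(D, dims, S = 100, engine = c("cpp", "r"),
                           max_retry = 50, degen_tol = 1e-12) {
  engine <- match.arg(engine)
  D <- as_distance_matrix(D)
  N <- nrow(D)
  dims <- as.integer(dims)
  if (length(dims) < 1L || any(dims < 1L)) stop("tested dimensions must be >= 1")
  if (any(diff(dims) != 1L)) stop("tested dimensions must be consecutive")
  if (max(dims) + 1L > N - 1L) {
    stop("largest tested dimension ", max(dims),
         " requires more points than available (N = ", N, ")")
  }
  if (S < 1L) stop("'S' must be a positive integer")

  if (engine == "cpp") {
    res <- cpp_height_profile(D^2, dims, as.integer(S),
                              as.integer(max_retry), degen_tol)
    med <- res$median_heights
    degen <- res$degenerate_counts
    nneg <- res$n_negative_sq
  } else {
    med <- matrix(0, N, length(dims))
    degen <- matrix(0L, N, length(dims))
    nneg <- 0
    for (a in seq_along(dims)) {
      n <- dims[a]
      for (i in seq_len(N)) {
        hs <- numeric(S)
        for (s in seq_len(S)) {
          h <- NA_real_
          for (r in seq_len(max_retry + 1L)) {
            idx <- sample_simplex_partners(i, n, N)
            h <- apex_height(D[idx, idx, drop = FALSE], D[i, idx],
                             tol = degen_tol)
            if (!is.na(h)) break
            degen[i, a] <- degen[i, a] + 1L
          }
          if (is.na(h) || degen[i, a] > 50L * S) {
            stop("height profile: point ", i, " at tested dimension ", n,
                 " exceeded the degenerate-simplex retry budget")
          }
          hs[s] <- h
        }
        med[i, a] <- stats::median(hs)
      }
    }
  }

  dimnames(med) <- list(rownames(D), paste0("n", dims))
  structure(list(
    median_heights = med,
    h_mean = colMeans(med),
    h_sd = apply(med, 2, sd_pop),
    dims = dims,
    degenerate_counts = degen,
    n_negative_sq = nneg,
    S = S
  ), class = "orthomds_profile")
}

#' Estimate the main-subspace dimension from a height profile
#'
#' Returns the tested dimension maximizing the ratio of consecutive mean
#' median heights, \eqn{\bar n = \arg\max_n \tilde h_{n-1} / \tilde h_n}.
#' The first tested dimension is excluded (it has no predecessor), a guard
#' of \code{eps} is added to every denominator, and ties break toward the
#' smallest dimension.
#'
#' @param profile an \code{"orthomds_profile"} object from [height_profile()].
#' @param eps denominator guard.
#' @return the estimated dimension (integer), with the ratio curve attached
#'   as attribute \code{"ratios"}.
#' @export
estimate_dimension <- function(profile, eps = 1e-12) {
  stopifnot(inherits(profile, "orthomds_profile"))
  h <- profile$h_mean
  if (length(h) < 2L) stop("need at least two consecutive tested dimensions")
  if (all(h < eps)) {
    stop("all mean heights are (numerically) zero; cannot form height ratios")
  }
  ratios <- h[-length(h)] / (h[-1L] + eps)
  names(ratios) <- paste0("n", profile$dims[-1L])
  n_raw <- profile$dims[-1L][which.max(ratios)]
  structure(n_raw, ratios = ratios)
}

#' Flag orthogonal outliers at a tested dimension
#'
#' A point is flagged when its median height at dimension \code{n} exceeds
#' the mean plus \code{c} population standard deviations of the height
#' distribution at that dimension (strict inequality):
#' \eqn{O = \{ i : h_i^n > \tilde h_n + c\,\sigma_n \}}.
#'
#' @inheritParams estimate_dimension
#' @param n dimension at which to threshold (must be among the profile's
#'   tested dimensions); typically the estimate from [estimate_dimension()].
#' @param c positive threshold multiplier (default 3, the three-sigma rule).
#' @return integer vector of flagged point indices (possibly empty), named
#'   with point labels when available.
#' @export
detect_outliers <- function(profile, n, c = 3) {
  stopifnot(inherits(profile, "orthomds_profile"), c > 0)
  a <- match(n, profile$dims)
  if (is.na(a)) stop("dimension ", n, " is not among the tested dimensions")
  h <- profile$median_heights[, a]
  which(h > mean(h) + c * sd_pop(h))
}

#' Debias a dimension estimate for the outlier fraction
#'
#' Sampled bases occasionally contain outliers, which inflates the apparent
#' hull dimension; with an outlier fraction p, the number of outliers in a
#' base of n+1 points is hypergeometric with expectation (n+1)p. The raw
#' estimate is corrected by the integer part of that expectation:
#' \eqn{n^* = \bar n - \lfloor (\bar n + 1) p \rfloor}, floored at 1.
#'
#' @param n_raw raw dimension estimate.
#' @param p_hat measured outlier fraction in \code{[0, 1]}.
#' @return list with the bias \code{delta} and the debiased \code{n_star}.
#' @examples
#' debias_dimension(42, 0.05) # delta 2, n* 40
#' @export
debias_dimension <- function(n_raw, p_hat) {
  stopifnot(n_raw >= 1, p_hat >= 0, p_hat <= 1)
  delta <- floor((n_raw + 1) * p_hat)
  list(delta = as.integer(delta), n_star = as.integer(max(n_raw - delta, 1)))
}

# population (divide-by-N) standard deviation; the estimator's threshold
# convention
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
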