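#' Robust MDS with orthogonal-outlier detection and correction
#'
#' Fits the full pipeline on a pairwise dissimilarity matrix (or on raw
#' coordinates): estimate the main-subspace dimension from sampled
#' simplex-height profiles, flag orthogonal outliers, debias the dimension
#' estimate for the measured outlier fraction, embed the data by classical
#' MDS (skipped when coordinates are supplied), and project the outliers
#' onto the main subspace fitted through the regular points, yielding a
#' corrected distance matrix.
#'
#' The tested dimensions must stay below the affine rank of the
#' configuration: at and beyond the rank, every sampled simplex is flat and
#' its height vanishes identically, which would make the height-ratio
#' criterion spurious. \code{orthomds()} therefore caps \code{dims} at
#' rank - 1 (with a warning when the cap bites).
#'
#' @param d symmetric pairwise distance matrix, \code{dist} object, or
#'   \code{NULL} when \code{coords} is given (distances are then computed as
#'   Euclidean distances of the rows).
#' @param coords optional N x d coordinate matrix; when supplied, the MDS
#'   embedding step is skipped and the correction operates on these
#'   coordinates directly.
#' @param dims integer vector of consecutive dimensions to test; default
#'   \code{1:min(N - 2, 50)}, capped at the affine rank minus one.
#' @param S simplices sampled per point and dimension (default 100).
#' @param c outlier threshold multiplier (default 3, three-sigma rule).
#' @param seed optional integer seed (calls [set.seed()]).
#' @param project_dim project outliers onto the subspace of the debiased
#'   dimension \code{"debiased"} (default) or the raw estimate \code{"raw"}.
#' @param engine height-profile engine, see [height_profile()].
#' @return an object of class \code{"orthomds"}; see Details.
#'
#' @details The returned object is a list with components
#' \describe{
#'   \item{n_raw}{raw dimension estimate (argmax of the height-ratio curve)}
#'   \item{outliers}{flagged point indices (named when labels are present)}
#'   \item{p_hat}{measured outlier fraction}
#'   \item{delta, n_star}{hypergeometric bias and debiased dimension}
#'   \item{profile}{the \code{"orthomds_profile"} object}
#'   \item{ratios}{the height-ratio curve over tested dimensions}
#'   \item{embedding}{coordinates used for correction and their source}
#'   \item{basis}{fitted subspace (center and orthonormal directions)}
#'   \item{corrected_coords, corrected_D}{coordinates and distances after
#'     projecting the outliers}
#' }
#'
#' @examples
#' set.seed(7)
#' sim <- sim_cross()
#' fit <- orthomds(sim_dist(sim), dims = 1:2, S = 50)
#' fit
#' @export
orthomds <- function(d = NULL, coords = NULL, dims = NULL, S = 100, c = 3,
                     seed = NULL, project_dim = c("debiased", "raw"),
                     engine = c("cpp", "r")) {
  project_dim <- match.arg(project_dim)
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(d) && is.null(coords)) {
    stop("supply a distance matrix 'd' and/or a coordinate matrix 'coords'")
  }
  if (!is.null(coords)) coords <- as.matrix(coords)
  if (is.null(d)) {
    D <- full_dist(coords)
  } else {
    D <- as_distance_matrix(d)
    if (!is.null(coords) && nrow(coords) != nrow(D)) {
      stop("'coords' and 'd' disagree on the number of points")
    }
  }
  N <- nrow(D)
  if (N < 4L) stop("need at least 4 points")

  # coordinates for the correction stage (and the rank bound on dims)
  if (!is.null(coords)) {
    ctr <- scale(coords, scale = FALSE)
    sv <- svd(ctr, nu = 0, nv = 0)$d
    rank <- sum(sv > 1e-9 * max(sv))
    embedding <- structure(list(coords = coords, rank = rank,
                                n_clipped = 0L, source = "input-coordinates"),
                           class = "orthomds_embedding")
  } else {
    embedding <- mds_embed(D)
    rank <- embedding$rank
  }

  if (is.null(dims)) dims <- seq_len(min(N - 2L, 50L))
  dims <- as.integer(dims)
  if (max(dims) > rank - 1L) {
    dims <- dims[dims <= rank - 1L]
    if (length(dims) < 2L) {
      stop("fewer than two tested dimensions remain below the affine rank (",
           rank, ") of the configuration")
    }
    warning("tested dimensions capped at the affine rank minus one (",
            rank - 1L, "): heights vanish identically at and beyond the rank")
  }

  profile <- height_profile(D, dims, S = S, engine = engine)
  n_raw <- estimate_dimension(profile)
  ratios <- attr(n_raw, "ratios")
  n_raw <- as.integer(n_raw)
  outliers <- detect_outliers(profile, n_raw, c = c)
  p_hat <- length(outliers) / N
  db <- debias_dimension(n_raw, p_hat)
  proj_dim <- if (project_dim == "debiased") db$n_star else n_raw
  proj_dim <- min(proj_dim, ncol(embedding$coords))

  regular <- setdiff(seq_len(N), outliers)
  if (length(outliers) && length(regular) > proj_dim) {
    basis <- fit_subspace(embedding$coords, regular, proj_dim)
    corr <- project_outliers(embedding$coords, outliers, basis)
  } else {
    if (length(outliers)) {
      warning("too few regular points to fit the subspace; ",
              "no correction applied")
    }
    basis <- NULL
    corr <- list(coords = embedding$coords, D = full_dist(embedding$coords))
  }

  structure(list(
    call = match.call(),
    N = N, D = D,
    config = list(S = S, c = c, dims = dims, seed = seed,
                  project_dim = project_dim, engine = engine),
    profile = profile,
    n_raw = n_raw, ratios = ratios,
    outliers = outliers, p_hat = p_hat,
    delta = db$delta, n_star = db$n_star,
    project_dim_used = proj_dim,
    embedding = embedding, basis = basis,
    corrected_coords = corr$coords,
    corrected_D = corr$D
  ), class = "orthomds")
}

#' @export
print.orthomds <- function(x, ...) {
  cat("Robust MDS with orthogonal-outlier correction\n")
  cat(sprintf("  %d points; tested dimensions %d..%d (S = %d, c = %g)\n",
              x$N, min(x$config$dims), max(x$config$dims),
              x$config$S, x$config$c))
  cat(sprintf("  raw dimension estimate:      %d\n", x$n_raw))
  cat(sprintf("  outliers flagged:            %d (fraction %.3g)\n",
              length(x$outliers), x$p_hat))
  cat(sprintf("  debiased dimension estimate: %d (bias %d)\n",
              x$n_star, x$delta))
  invisible(x)
}

#' @export
summary.orthomds <- function(object, ...) {
  tab <- data.frame(
    dim = object$profile$dims,
    h_mean = object$profile$h_mean,
    h_sd = object$profile$h_sd,
    ratio = c(NA, object$ratios),
    row.names = NULL
  )
  out <- list(fit = object, table = tab,
              outlier_labels = names(object$outliers))
  class(out) <- "summary.orthomds"
  out
}

#' @export
print.summary.orthomds <- function(x, ...) {
  print(x$fit)
  cat("\nHeight profile (mean and population sd of per-point medians):\n")
  print(x$table, digits = 4)
  if (length(x$fit$outliers)) {
    cat("\nOutliers:",
        paste(if (is.null(x$outlier_labels)) x$fit$outliers
              else x$outlier_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a fitted orthomds object
#'
#' Two panels: the per-point median height distributions across tested
#' dimensions (one boxplot per dimension), and the consecutive height-ratio
#' curve whose argmax is the raw dimension estimate.
#'
#' @param x an \code{"orthomds"} object.
#' @param ... passed to [boxplot()].
#' @export
plot.orthomds <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  boxplot(x$profile$median_heights, names = x$profile$dims,
          xlab = "tested dimension n", ylab = "median height",
          main = "Height profile", ...)
  plot(x$profile$dims[-1L], x$ratios, type = "b", pch = 16,
       xlab = "tested dimension n", ylab = "ratio of mean heights",
       main = "Dimension criterion")
  abline(v = x$n_raw, lty = 2)
  invisible(x)
}

#' Estimated orthogonal distances of each point
#'
#' Residuals of the fit: the per-point median height at the estimated
#' dimension, which approximates each point's distance to the main
#' subspace. Outliers are the points whose residual exceeds the
#' mean + c * sd threshold.
#'
#' @param object an \code{"orthomds"} object.
#' @param ... unused.
#' @export
residuals.orthomds <- function(object, ...) {
  object$profile$median_heights[, match(object$n_raw, object$profile$dims)]
}
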