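#' Simulate a planar cross with orthogonal outliers
#'
#' Lays \code{n_points} evenly along two perpendicular unit segments through
#' the origin of the plane z = 0, then gives \code{n_outliers} randomly
#' chosen points a third coordinate of random sign and magnitude uniform in
#' \code{amp_bounds}. A small test scene: the main subspace is the plane
#' (true dimension 2) and the outliers are displaced purely orthogonally.
#'
#' @param n_points total number of points (default 25).
#' @param n_outliers number of points displaced orthogonally (default 3).
#' @param arm_halfwidth half-length of each cross arm.
#' @param amp_bounds bounds for the orthogonal displacement magnitude.
#' @return an object of class \code{"orthomds_sim"}: list with \code{coords}
#'   (n_points x 3), \code{true_dim = 2}, \code{outlier_idx}, and the
#'   generation parameters.
#' @export
sim_cross <- function(n_points = 25, n_outliers = 3, arm_halfwidth = 1,
                      amp_bounds = c(10, 30)) {
  stopifnot(n_outliers <= n_points, n_points >= 4)
  n1 <- ceiling(n_points / 2)
  n2 <- n_points - n1
  coords <- matrix(0, n_points, 3)
  coords[seq_len(n1), 1] <- seq(-arm_halfwidth, arm_halfwidth, length.out = n1)
  coords[n1 + seq_len(n2), 2] <- seq(-arm_halfwidth, arm_halfwidth,
                                     length.out = n2)
  out <- sort(sample.int(n_points, n_outliers))
  if (n_outliers > 0) {
    amp <- runif(n_outliers, min(amp_bounds), max(amp_bounds))
    coords[out, 3] <- amp * sample(c(-1, 1), n_outliers, replace = TRUE)
  }
  rownames(coords) <- paste0("p", seq_len(n_points))
  structure(list(coords = coords, true_dim = 2L, outlier_idx = out,
                 outlier_fraction = n_outliers / n_points,
                 noise_var = 0, amp_bounds = amp_bounds),
            class = "orthomds_sim")
}

#' Simulate a Gaussian main subspace with planted orthogonal outliers
#'
#' Regular points have standard-Gaussian coordinates in the first
#' \code{d_star} dimensions; all ambient coordinates (main and orthogonal)
#' additionally receive isotropic Gaussian noise of variance
#' \code{noise_var}. A fraction \code{p} of the points is planted as
#' orthogonal outliers: each gets, in one randomly chosen orthogonal
#' coordinate, a displacement drawn uniformly from \code{amp_bounds} and
#' redrawn until its magnitude is at least \code{min_amp}, so that no
#' planted outlier sits at noise scale.
#'
#' The ambient dimension is \code{d_star + extra_dims}. The default
#' \code{extra_dims = 50} keeps the ambient dimension well above any tested
#' dimension window: when the tested dimension approaches the ambient
#' dimension, sampled simplices lose orthogonal room and their heights
#' collapse for reasons unrelated to the data's structure.
#'
#' @param N number of points.
#' @param d_star true main-subspace dimension.
#' @param extra_dims number of orthogonal coordinates.
#' @param p outlier fraction; \code{round(p * N)} points are planted.
#' @param noise_var isotropic noise variance (default 2e-4).
#' @param amp_bounds support of the uniform orthogonal displacement.
#' @param min_amp redraw floor for the displacement magnitude.
#' @return an \code{"orthomds_sim"} object (see [sim_cross()]).
#' @export
sim_gaussian_subspace <- function(N, d_star, extra_dims = 50, p = 0.05,
                                  noise_var = 2e-4, amp_bounds = c(-30, 30),
                                  min_amp = 10) {
  stopifnot(N >= 4, d_star >= 1, extra_dims >= 1, p >= 0, p < 1)
  d <- d_star + extra_dims
  coords <- matrix(rnorm(N * d, sd = sqrt(noise_var)), N, d)
  coords[, seq_len(d_star)] <- coords[, seq_len(d_star)] + rnorm(N * d_star)
  n_out <- round(p * N)
  out <- integer(0)
  if (p > 0 && n_out < 1) {
    warning("p * N < 1: no outliers planted")
  } else if (n_out > 0) {
    out <- sort(sample.int(N, n_out))
    axis <- d_star + sample.int(extra_dims, n_out, replace = TRUE)
    amp <- vapply(seq_len(n_out), function(k) {
      repeat {
        a <- runif(1, min(amp_bounds), max(amp_bounds))
        if (abs(a) >= min_amp) return(a)
      }
    }, numeric(1))
    coords[cbind(out, axis)] <- amp
  }
  rownames(coords) <- paste0("p", seq_len(N))
  structure(list(coords = coords, true_dim = as.integer(d_star),
                 outlier_idx = out, outlier_fraction = n_out / N,
                 noise_var = noise_var, amp_bounds = amp_bounds),
            class = "orthomds_sim")
}

#' Euclidean distance matrix of a simulated dataset
#'
#' @param sim an \code{"orthomds_sim"} object, or any coordinate matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
sim_dist <- function(sim) {
  full_dist(if (inherits(sim, "orthomds_sim")) sim$coords else as.matrix(sim))
}

#' Ground-truth corrected distances of a simulated dataset
#'
#' Replaces every planted outlier by its exact orthogonal projection onto
#' the true main subspace (zeroing its orthogonal coordinates) and returns
#' the resulting distance matrix. This is the reference against which a
#' corrected distance matrix can be judged (e.g. by Shepard RMSE).
#'
#' @param sim an \code{"orthomds_sim"} object.
#' @return symmetric distance matrix with zero diagonal.
#' @export
true_corrected_dist <- function(sim) {
  stopifnot(inherits(sim, "orthomds_sim"))
  x <- sim$coords
  if (length(sim$outlier_idx)) {
    x[sim$outlier_idx, -seq_len(sim$true_dim)] <- 0
  }
  full_dist(x)
}

#' @export
print.orthomds_sim <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$coords), "points in", ncol(x$coords),
      "dimensions\n")
  cat("  true main-subspace dimension:", x$true_dim, "\n")
  cat("  planted outliers:", length(x$outlier_idx),
      sprintf("(fraction %.3g)\n", x$outlier_fraction))
  invisible(x)
}
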