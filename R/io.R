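#' Coerce input to a validated distance matrix
#'
#' Accepts a \code{dist} object or a square numeric matrix; checks symmetry
#' (tolerance 1e-8 relative), a zero diagonal and nonnegative entries, and
#' reports the worst offending entry on failure.
#'
#' @param d candidate distance input.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (inherits(d, "orthomds_sim")) {
    stop("pass sim_dist(sim) or sim$coords, not the simulation object")
  }
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (!is.numeric(d) || anyNA(d)) stop("distance matrix has missing or non-numeric entries")
  asym <- abs(d - t(d))
  tol <- 1e-8 * max(1, max(abs(d)))
  if (any(asym > tol)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "distance matrix is asymmetric beyond tolerance at entry (%d, %d): %g vs %g",
      w[1], w[2], d[w[1], w[2]], d[w[2], w[1]]))
  }
  if (any(abs(diag(d)) > tol)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be nonnegative")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Read a distance or coordinate matrix from delimited text
#'
#' Reads a rectangular numeric table; a header row and/or a leading label
#' column are auto-detected (any non-numeric first row/column). With
#' \code{kind = "distance"} the matrix is validated as a distance matrix;
#' with \code{kind = "coords"} the rows are taken as coordinates and the
#' Euclidean distance matrix is returned alongside them.
#'
#' @param path file path.
#' @param kind \code{"distance"} or \code{"coords"}.
#' @param delimiter field separator (default comma).
#' @return for \code{"distance"}, the validated matrix; for
#'   \code{"coords"}, a list with \code{coords} and \code{D}.
#' @export
read_matrix <- function(path, kind = c("distance", "coords"),
                        delimiter = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           stringsAsFactors = FALSE)
  is_num <- function(x) !anyNA(suppressWarnings(as.numeric(x)))
  # a header row shows non-numeric entries beyond any leading label column
  header <- !all(vapply(raw[1, -1, drop = FALSE], is_num, logical(1)))
  if (header) {
    nm <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
  }
  labels_col <- !is_num(raw[[1]])
  lab <- NULL
  if (labels_col) {
    lab <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
    if (header) nm <- nm[-1]
  }
  m <- as.matrix(as.data.frame(lapply(raw, as.numeric)))
  if (anyNA(m)) stop("non-numeric or missing entries in ", path)
  rownames(m) <- lab
  colnames(m) <- if (header && length(nm) == ncol(m)) nm else NULL
  if (kind == "distance") {
    as_distance_matrix(m)
  } else {
    list(coords = m, D = full_dist(m))
  }
}

#' Write a matrix as delimited text
#'
#' @param m matrix to write.
#' @param path output path.
#' @param delimiter field separator.
#' @export
write_matrix <- function(m, path, delimiter = ",") {
  utils::write.table(m, path, sep = delimiter, quote = FALSE,
                     row.names = !is.null(rownames(m)), col.names = FALSE)
  invisible(path)
}

#' Run summary of a fitted orthomds object
#'
#' A serializable record of one run: configuration echo, the dimension
#' estimates, outliers, per-dimension height statistics and numerical
#' warnings (degenerate draws, sign-anomalous determinants, clipped MDS
#' eigenvalues). A run is reproducible from its summary alone.
#'
#' @param fit an \code{"orthomds"} object.
#' @return a named list.
#' @export
run_summary <- function(fit) {
  stopifnot(inherits(fit, "orthomds"))
  labels <- rownames(fit$D)
  list(
    config = list(S = fit$config$S, c = fit$config$c,
                  dims = fit$config$dims,
                  seed = fit$config$seed,
                  project_dim = fit$config$project_dim),
    n_points = fit$N,
    n_raw = fit$n_raw,
    n_star = fit$n_star,
    delta = fit$delta,
    p_hat = fit$p_hat,
    outliers = as.integer(fit$outliers),
    outlier_labels = if (is.null(labels)) NULL else labels[fit$outliers],
    h_mean = as.numeric(fit$profile$h_mean),
    h_sd = as.numeric(fit$profile$h_sd),
    degenerate_draws = sum(fit$profile$degenerate_counts),
    negative_sq_volumes = fit$profile$n_negative_sq,
    clipped_eigenvalues = fit$embedding$n_clipped,
    embedding_source = fit$embedding$source
  )
}

#' Write a run summary as JSON
#'
#' @inheritParams run_summary
#' @param path output path.
#' @export
write_run_summary <- function(fit, path) {
  jsonlite::write_json(run_summary(fit), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
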