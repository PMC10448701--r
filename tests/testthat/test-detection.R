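test_that("simplex partner sampling honors its contract", {
  set.seed(1)
  # only one possible choice
  expect_setequal(sample_simplex_partners(1, 2, 4), 2:4)
  s <- sample_simplex_partners(5, 3, 100)
  expect_length(s, 4)
  expect_false(any(duplicated(s)))
  expect_false(5 %in% s)
  set.seed(99); a <- replicate(5, sample_simplex_partners(3, 2, 20))
  set.seed(99); b <- replicate(5, sample_simplex_partners(3, 2, 20))
  expect_identical(a, b)
  expect_error(sample_simplex_partners(1, 5, 6), "partners")
})

test_that("height profiles recover exact orthogonal offsets", {
  set.seed(7)
  X <- cbind(matrix(rnorm(60), 30, 2), 0)
  X <- rbind(X, c(0.5, -0.1, 7))
  D <- edist(X)
  for (eng in c("cpp", "r")) {
    set.seed(11)
    pr <- height_profile(D, 1:2, S = 50, engine = eng)
    # coplanar regular points: heights at n = 2 vanish
    expect_lt(max(pr$median_heights[1:30, 2]), 1e-7)
    # the offset point's height is its distance to the plane, within 1%
    expect_equal(pr$median_heights[31, 2], 7, tolerance = 0.01)
    expect_equal(pr$h_mean, colMeans(pr$median_heights))
    expect_true(all(pr$median_heights >= 0))
  }
})

test_that("height profiles are reproducible and validate input", {
  D <- edist(matrix(rnorm(40), 10))
  set.seed(5); a <- height_profile(D, 1:3, S = 20)
  set.seed(5); b <- height_profile(D, 1:3, S = 20)
  expect_identical(a$median_heights, b$median_heights)
  expect_error(height_profile(D, c(1, 3), S = 10), "consecutive")
  expect_error(height_profile(D, 1:9, S = 10), "more points")
  expect_error(height_profile(D, 1:2, S = 0), "positive")
})

test_that("an S = 1 profile equals a single-draw height", {
  set.seed(13)
  X <- matrix(rnorm(8 * 3), 8)
  D <- edist(X)
  set.seed(21)
  pr <- height_profile(D, 2:3, S = 1, engine = "r")
  set.seed(21)
  for (n in 2:3) for (i in 1:8) {
    idx <- sample_simplex_partners(i, n, 8)
    expect_equal(pr$median_heights[i, n - 1],
                 apex_height(D[idx, idx], D[i, idx]))
  }
})

test_that("dimension estimation maximizes the consecutive height ratio", {
  mk <- function(h, dims) structure(
    list(h_mean = h, dims = dims, median_heights = NULL),
    class = "orthomds_profile")
  expect_equal(as.integer(estimate_dimension(mk(c(5, 4.9, 0.01, 0.009), 1:4))), 3L)
  # all ratios equal: tie broken toward the smallest eligible dimension
  expect_equal(as.integer(estimate_dimension(mk(2^-(1:6), 1:6))), 2L)
  expect_error(estimate_dimension(mk(rep(0, 4), 1:4)), "zero")
  expect_error(estimate_dimension(mk(5, 1)), "two consecutive")
})

test_that("outlier flagging uses the strict mean + c sd rule", {
  mk <- function(h, dims = 1:2) structure(
    list(h_mean = colMeans(h), dims = dims, median_heights = h),
    class = "orthomds_profile")
  h <- cbind(rep(1, 100), c(rep(0.1, 99), 10))
  # population sd of the n=2 column is ~0.98; threshold ~3.14 flags only 10.0
  expect_identical(detect_outliers(mk(h), 2, c = 3), 100L)
  expect_length(detect_outliers(mk(h), 2, c = 1e6), 0)
  flat <- cbind(rep(1, 20), rep(2, 20))
  expect_length(detect_outliers(mk(flat), 2, c = 3), 0)
  expect_error(detect_outliers(mk(h), 5, c = 3), "not among")
})

test_that("hypergeometric debiasing follows floor((n+1) p)", {
  expect_equal(debias_dimension(42, 0.05), list(delta = 2L, n_star = 40L))
  expect_equal(debias_dimension(10, 0), list(delta = 0L, n_star = 10L))
  expect_equal(debias_dimension(3, 0.0662), list(delta = 0L, n_star = 3L))
  # floor at 1 for extreme fractions
  expect_equal(debias_dimension(2, 0.9)$n_star, 1L)
  # monotone in p for fixed n
  d <- vapply(seq(0, 1, 0.05), function(p) debias_dimension(20, p)$delta, 1L)
  expect_true(all(diff(d) >= 0))
})

test_that("detection decisions are scale-invariant", {
  set.seed(31)
  sim <- sim_gaussian_subspace(60, 2, extra_dims = 6, p = 0.05)
  D <- sim_dist(sim)
  set.seed(77); f1 <- orthomds(D, dims = 1:5, S = 30)
  set.seed(77); f2 <- orthomds(37 * D, dims = 1:5, S = 30)
  expect_identical(f1$n_raw, f2$n_raw)
  expect_identical(f1$outliers, f2$outliers)
  expect_identical(f1$n_star, f2$n_star)
  expect_equal(37 * f1$profile$h_mean, f2$profile$h_mean)
})

test_that("permuting point labels permutes outliers, not the estimates", {
  set.seed(32)
  sim <- sim_gaussian_subspace(50, 2, extra_dims = 5, p = 0.06)
  D <- sim_dist(sim)
  p <- sample(50)
  set.seed(5); f1 <- orthomds(D, dims = 1:4, S = 40)
  set.seed(5); f2 <- orthomds(D[p, p], dims = 1:4, S = 40)
  expect_identical(f1$n_raw, f2$n_raw)
  expect_identical(f1$n_star, f2$n_star)
  expect_setequal(match(p[f2$outliers], seq_len(50)), as.integer(f1$outliers))
})

test_that("the pipeline recovers planted low-dimensional structure", {
  # clean Gaussian plane: dimension 2; the strict three-sigma rule still has
  # a small false-flag rate on pure noise heights, so allow a stray flag
  set.seed(51)
  sim <- sim_gaussian_subspace(80, 2, extra_dims = 8, p = 0)
  fit <- orthomds(sim_dist(sim), dims = 1:6, S = 40)
  expect_identical(fit$n_star, 2L)
  expect_lte(length(fit$outliers), 2)
  expect_identical(fit$delta, 0L)

  # replicated recovery with planted outliers
  hits_dim <- 0; prec <- c(); rec <- c()
  for (s in 1:5) {
    set.seed(500 + s)
    sim <- sim_gaussian_subspace(200, 2, p = 0.05)
    fit <- orthomds(sim_dist(sim), dims = 1:8, S = 50)
    hits_dim <- hits_dim + (fit$n_star == 2L)
    hit <- length(intersect(fit$outliers, sim$outlier_idx))
    prec <- c(prec, hit / max(1, length(fit$outliers)))
    rec <- c(rec, hit / length(sim$outlier_idx))
  }
  expect_gte(hits_dim, 4)
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.7)
})
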