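test_that("classical MDS recovers Euclidean configurations isometrically", {
  # collinear points at 0, 3, 7
  D <- edist(matrix(c(0, 3, 7), 3))
  emb <- mds_embed(D)
  expect_equal(edist(emb$coords), D, tolerance = 1e-10)
  # unit square corners: distance multiset preserved
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  emb <- mds_embed(edist(sq))
  expect_equal(sort(edist(emb$coords)[upper.tri(diag(4))]),
               sort(c(1, 1, 1, 1, sqrt(2), sqrt(2))), tolerance = 1e-10)
})

test_that("MDS embedding dimension equals the affine rank", {
  set.seed(61)
  for (r in c(1, 3, 5)) {
    X <- matrix(rnorm(20 * r), 20) %*% matrix(rnorm(r * 8), r)
    emb <- mds_embed(edist(X))
    expect_identical(emb$rank, as.integer(r))
    expect_identical(ncol(emb$coords), as.integer(r))
  }
  expect_error(mds_embed(edist(matrix(rnorm(10), 5)), target_dim = 5), "N - 1")
})

test_that("subspace fitting spans the regular points exactly", {
  set.seed(62)
  X <- cbind(matrix(rnorm(40), 20, 2), 0)
  X[20, 3] <- 9 # one off-plane point
  basis <- fit_subspace(X, 1:19, 2)
  expect_equal(dim(basis$rotation), c(3L, 2L))
  expect_equal(unname(crossprod(basis$rotation)), diag(2), tolerance = 1e-12)
  # residual of every regular point is zero
  R <- sweep(X[1:19, ], 2, basis$center)
  resid <- R - R %*% basis$rotation %*% t(basis$rotation)
  expect_lt(max(abs(resid)), 1e-12)
  # points on a line: single direction parallel to it
  L <- outer(seq(-2, 2, length.out = 10), c(1, 2, -1))
  b1 <- fit_subspace(L, 1:10, 1)
  expect_equal(abs(sum(b1$rotation * c(1, 2, -1) / sqrt(6))), 1,
               tolerance = 1e-10)
  expect_error(fit_subspace(X, 1:2, 2), "regular points")
})

test_that("full-rank bases make projection the identity", {
  set.seed(63)
  X <- matrix(rnorm(30), 10, 3)
  basis <- fit_subspace(X, 1:8, 3)
  pr <- project_outliers(X, 9:10, basis)
  expect_equal(pr$coords, X, tolerance = 1e-10)
})

test_that("outlier projection is orthogonal onto the fitted plane", {
  set.seed(64)
  X <- cbind(matrix(rnorm(30), 15, 2), 0)
  X <- rbind(X, c(1, 2, 5))
  basis <- fit_subspace(X, 1:15, 2)
  pr <- project_outliers(X, 16L, basis)
  expect_equal(pr$coords[16, ], c(1, 2, 0), tolerance = 1e-10)
  expect_equal(pr$coords[1:15, ], X[1:15, ])
  expect_equal(unname(pr$D), unname(edist(pr$coords)))
  # a point already in the subspace is a fixed point
  X2 <- rbind(X[1:15, ], c(0.3, -0.4, 0))
  pr2 <- project_outliers(X2, 16L, fit_subspace(X2, 1:15, 2))
  expect_equal(pr2$coords[16, ], X2[16, ], tolerance = 1e-10)
  # empty outlier set: distances unchanged
  pr3 <- project_outliers(X, integer(0), basis)
  expect_identical(pr3$coords, X)
})

test_that("coordinate and distance inputs give matching corrections", {
  set.seed(65)
  sim <- sim_gaussian_subspace(60, 2, extra_dims = 4, p = 0.05)
  set.seed(9); f1 <- orthomds(coords = sim$coords, dims = 1:5, S = 40)
  set.seed(9); f2 <- orthomds(sim_dist(sim), dims = 1:5, S = 40)
  expect_identical(f1$n_star, f2$n_star)
  expect_identical(f1$outliers, f2$outliers)
  expect_equal(f1$corrected_D, f2$corrected_D, tolerance = 1e-6)
})

test_that("correction preserves regular distances and kills residuals", {
  set.seed(66)
  sim <- sim_gaussian_subspace(80, 3, extra_dims = 5, p = 0.05)
  fit <- orthomds(sim_dist(sim), dims = 1:6, S = 50)
  expect_gt(length(fit$outliers), 0)
  reg <- setdiff(1:80, fit$outliers)
  emb_D <- edist(fit$embedding$coords)
  expect_equal(fit$corrected_D[reg, reg], emb_D[reg, reg], tolerance = 1e-10)
  # former outliers now sit in the fitted subspace
  R <- sweep(fit$corrected_coords[fit$outliers, , drop = FALSE], 2,
             fit$basis$center)
  resid <- R - R %*% fit$basis$rotation %*% t(fit$basis$rotation)
  expect_lt(max(abs(resid)), 1e-8)
  # projecting again changes nothing
  pr <- project_outliers(fit$corrected_coords, fit$outliers, fit$basis)
  expect_equal(pr$coords, fit$corrected_coords, tolerance = 1e-12)
})
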