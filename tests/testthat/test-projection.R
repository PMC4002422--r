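test_that("class-conditional pairwise distances are valid and symmetric", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 3), 20, 2))
  labs <- rep(c("a", "b"), each = 20)
  D <- pairwise_class_distances(X, labs, shrink = 0)
  expect_identical(dim(D), c(40L, 40L))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # within-class block equals plain Mahalanobis under that class covariance
  Xa <- X[labs == "a", ]
  Sa <- speckletex:::ridge_cov(crossprod(sweep(Xa, 2, colMeans(Xa))) /
                                 nrow(Xa))
  expect_equal(D[1, 2], mahalanobis_dist(X[1, ], X[2, ], Sa),
               tolerance = 1e-10)
  # cross-class pair: mean of the two class-metric distances
  Xb <- X[labs == "b", ]
  Sb <- speckletex:::ridge_cov(crossprod(sweep(Xb, 2, colMeans(Xb))) /
                                 nrow(Xb))
  expect_equal(D[1, 21],
               (mahalanobis_dist(X[1, ], X[21, ], Sa) +
                  mahalanobis_dist(X[1, ], X[21, ], Sb)) / 2,
               tolerance = 1e-10)
})

test_that("a 3-4-5 triangle embeds exactly in the plane", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3; D[1, 3] <- D[3, 1] <- 4; D[2, 3] <- D[3, 2] <- 5
  emb <- sammon_project(D)
  expect_lt(emb$stress, 1e-10)
  expect_lt(max(abs(as.matrix(dist(emb$points)) - D)), 1e-6)
  expect_false(is.unsorted(rev(emb$stress_path)))
})

test_that("planar configurations are recovered up to rigid motion", {
  set.seed(10)
  P <- matrix(rnorm(40), 20, 2)
  D <- as.matrix(dist(P))
  emb <- sammon_project(D)
  expect_lt(emb$stress, 1e-8)
  # Procrustes residual after optimal rotation/reflection + translation
  A <- sweep(P, 2, colMeans(P))
  B <- sweep(emb$points, 2, colMeans(emb$points))
  sv <- svd(crossprod(B, A))
  R <- sv$u %*% t(sv$v)      # optimal rotation/reflection mapping B to A
  expect_lt(max(abs(B %*% R - A)), 1e-5)
})

test_that("stress decreases monotonically on a hard 10D cloud", {
  set.seed(11)
  X <- matrix(rnorm(500), 50, 10)
  D <- as.matrix(dist(X))
  emb <- sammon_project(D, max_iter = 200)
  expect_false(is.unsorted(rev(emb$stress_path)))
  expect_gt(emb$iterations_run, 0)
  # orthonormal principal axes ordered by variance
  expect_equal(sum(emb$mvp_axis^2), 1, tolerance = 1e-10)
  expect_equal(sum(emb$mvp_axis * emb$svp_axis), 0, tolerance = 1e-10)
  expect_gte(emb$variances[1], emb$variances[2])
})

test_that("our final stress is competitive with the reference optimizer", {
  skip_if_not_installed("MASS")
  set.seed(12)
  X <- matrix(rnorm(300), 30, 10)
  D <- as.matrix(dist(X))
  ours <- sammon_project(D, max_iter = 500)
  ref <- MASS::sammon(D, k = 2, trace = FALSE)
  # MASS reports stress with the same normalization
  expect_lt(ours$stress, ref$stress * 1.1 + 1e-12)
})

test_that("MDS initialization beats random initialization usually", {
  set.seed(13)
  wins <- 0
  for (i in 1:10) {
    X <- matrix(rnorm(200), 20, 10)
    D <- as.matrix(dist(X))
    s_mds <- sammon_project(D, seed = i, init = "mds")$stress
    s_rnd <- sammon_project(D, seed = i, init = "random")$stress
    wins <- wins + (s_mds <= s_rnd + 1e-12)
  }
  expect_gte(wins, 8)
})

test_that("malformed distance matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2)
  expect_error(sammon_project(D), "symmetric")
  D2 <- matrix(c(0, -1, -1, 0), 2)
  expect_error(sammon_project(D2), "nonnegative")
  D3 <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sammon_project(D3), "diagonal")
})

test_that("the Texture Index measures MVP displacement", {
  # two clouds separated purely along one axis
  set.seed(14)
  a <- cbind(rnorm(30, 0, 0.1), rnorm(30, 0, 0.1))
  b <- cbind(rnorm(30, 7, 0.1), rnorm(30, 0, 0.1))
  D <- as.matrix(dist(rbind(a, b)))
  emb <- sammon_project(D)
  ti <- texture_index(emb, 1:30, 31:60)
  expect_equal(abs(ti), 7, tolerance = 0.2)
  expect_equal(texture_index(emb, 1:30, 1:30), 0)
  expect_error(texture_index(emb, integer(0), 1:30), "nonempty")
})

test_that("TI magnitude is invariant to rigid rotation of the embedding", {
  set.seed(15)
  a <- cbind(rnorm(25, 0, 0.2), rnorm(25, 0, 0.2))
  b <- cbind(rnorm(25, 5, 0.2), rnorm(25, 1, 0.2))
  P <- rbind(a, b)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  D1 <- as.matrix(dist(P))
  D2 <- as.matrix(dist(P %*% R))
  t1 <- texture_index(sammon_project(D1), 1:25, 26:50)
  t2 <- texture_index(sammon_project(D2), 1:25, 26:50)
  expect_equal(abs(t1), abs(t2), tolerance = 1e-3)
})

test_that("COG confidence intervals follow the normal critical value", {
  expect_equal(unname(cog_with_ci(c(5, 5, 5, 5))["halfwidth"]), 0)
  expect_equal(qnorm(0.975), 1.96, tolerance = 0.005)
  r <- cog_with_ci(c(0, 2), level = 0.95)
  expect_equal(unname(r["mean"]), 1)
  expect_equal(unname(r["halfwidth"]), qnorm(0.975))  # sd sqrt(2)/sqrt(2)
  expect_error(cog_with_ci(3), "at least 2")
  r90 <- cog_with_ci(c(0, 2), level = 0.90)
  expect_lt(r90["halfwidth"], r["halfwidth"])
})

test_that("TI series are oriented, tested and carry intervals", {
  set.seed(16)
  n <- 12
  tps <- rep(c(10, 20, 30), each = n)
  drift <- rep(c(0, -2, -5), each = n)     # negative drift: must be flipped
  P <- cbind(rnorm(3 * n) * 0.3 + drift, rnorm(3 * n) * 0.3)
  emb <- sammon_project(as.matrix(dist(P)))
  ts <- ti_series(emb, tps)
  expect_identical(ts$timepoint, c(10, 20, 30))
  expect_equal(ts$ti[1], 0)
  expect_gte(ts$ti[3], 0)                  # oriented positive at the end
  expect_true(is.na(ts$p_value[1]))
  expect_lt(ts$p_value[3], 1e-6)
  expect_true(all(ts$ci_halfwidth > 0))
})

test_that("null TI stays inside its permutation bound", {
  set.seed(18)
  inside <- 0
  for (r in 1:20) {
    X <- matrix(rnorm(30 * 3), 30, 3)     # one common distribution
    D <- as.matrix(dist(X))
    emb <- sammon_project(D, max_iter = 50)
    mv <- speckletex:::mvp_coords(emb)
    ti <- abs(mean(mv[16:30]) - mean(mv[1:15]))
    perm <- replicate(199, {
      i <- sample(30)
      abs(mean(mv[i[16:30]]) - mean(mv[i[1:15]]))
    })
    inside <- inside + (ti < quantile(perm, 0.99))
  }
  expect_gte(inside, 17)
})
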