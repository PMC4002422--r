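test_that("Mahalanobis distance matches closed forms", {
  expect_equal(mahalanobis_dist(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_dist(c(3, 4), c(0, 0), diag(2)), 5)
  expect_equal(mahalanobis_dist(c(2, 0), c(0, 0), diag(c(4, 1))), 1)
  expect_error(mahalanobis_dist(c(1, 0), c(0, 0),
                                matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("Mahalanobis is a metric and affine-invariant", {
  set.seed(17)
  for (i in 1:25) {
    d <- sample(2:5, 1)
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) + diag(d) * 0.1
    x <- rnorm(d); y <- rnorm(d); z <- rnorm(d)
    expect_equal(mahalanobis_dist(x, y, S), mahalanobis_dist(y, x, S))
    expect_lte(mahalanobis_dist(x, z, S),
               mahalanobis_dist(x, y, S) + mahalanobis_dist(y, z, S) + 1e-12)
    # invertible map T: distances unchanged under (Tx, Ty, T S T')
    Tm <- matrix(rnorm(d * d), d) + diag(d)
    expect_equal(mahalanobis_dist(Tm %*% x, Tm %*% y, Tm %*% S %*% t(Tm)),
                 mahalanobis_dist(x, y, S), tolerance = 1e-8)
  }
})

test_that("the symmetrized cross-cluster distance averages both metrics", {
  c1 <- list(mean = c(0, 0), cov = diag(c(4, 1)))
  c2 <- list(mean = c(2, 0), cov = diag(2))
  expect_equal(cross_cluster_distance(c1, c2), 1.5)  # mean(1, 2)
  expect_equal(cross_cluster_distance(c1, c1), 0)
  c3 <- list(mean = c(2, 0), cov = diag(c(4, 1)))
  expect_equal(cross_cluster_distance(c1, c3),
               mahalanobis_dist(c(0, 0), c(2, 0), diag(c(4, 1))))
})

test_that("AIC selects parsimonious mixtures on seeded draws", {
  set.seed(101)
  X1 <- matrix(rnorm(1000), 500, 2)
  f1 <- fit_class_gmm(X1, 1:4, seed = 101)
  expect_identical(f1$k, 1L)
  set.seed(102)
  X2 <- rbind(matrix(rnorm(500), 250, 2), matrix(rnorm(500, 10), 250, 2))
  f2 <- fit_class_gmm(X2, 1:2, seed = 102)
  expect_identical(f2$k, 2L)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  expect_equal(f2$aic,
               2 * speckletex:::gmm_n_params(2, 2) - 2 * f2$log_likelihood)
  # recovered centers near the generating means
  mns <- f2$means[order(f2$means[, 1]), ]
  expect_lt(max(abs(mns - rbind(c(0, 0), c(10, 10)))), 0.5)
})

test_that("AIC penalty is monotone at equal likelihood", {
  p1 <- speckletex:::gmm_n_params(1, 3)
  p2 <- speckletex:::gmm_n_params(2, 3)
  expect_gt(p2, p1)
  ll <- -100
  expect_gt(2 * p2 - 2 * ll, 2 * p1 - 2 * ll)
})

test_that("duplicated points yield the ridge-identity covariance", {
  X <- matrix(rep(c(1, 2), each = 10), 10, 2)
  f <- fit_class_gmm(X, 1, seed = 1)
  expect_equal(as.numeric(f$means), c(1, 2))
  S <- f$covariances[[1]]
  expect_equal(S[1, 2], 0)
  expect_equal(S[1, 1], S[2, 2])
  expect_lt(S[1, 1], 1e-9)   # epsilon-scaled identity
})

test_that("classification assigns by minimal distance with stable ties", {
  mA <- fit_class_gmm(matrix(rnorm(100), 50, 2), 1, seed = 1)
  mB <- fit_class_gmm(matrix(rnorm(100, 50), 50, 2), 1, seed = 1)
  r <- classify(mA$means[1, ], list(b = mB, a = mA))
  expect_identical(r$assigned_class, "a")
  expect_equal(unname(r$distances["a"]), 0)
  expect_gt(r$margin, 0)

  # exact tie: identical models under two labels -> lexicographic winner
  r2 <- classify(c(5, 5), list(zeta = mA, alpha = mA))
  expect_identical(r2$assigned_class, "alpha")
  expect_error(classify(c(0, 0), list()), "empty")

  set.seed(33)
  test <- rbind(matrix(rnorm(200), 100, 2), matrix(rnorm(200, 50), 100, 2))
  pred <- apply(test, 1, function(x)
    classify(x, list(a = mA, b = mB))$assigned_class)
  expect_gte(mean(pred == rep(c("a", "b"), each = 100)), 0.99)
})

test_that("leave-one-subset-out CV is perfect on separable classes", {
  set.seed(71)
  X <- rbind(matrix(rnorm(120), 60, 2), matrix(rnorm(120, 20), 60, 2))
  colnames(X) <- c("f1", "f2")
  M <- feature_matrix(X, rep(c("a", "b"), each = 60),
                      rep(sprintf("s%d", 1:6), 20))
  cv <- cross_validate(M, k_candidates = 1:2, seed = 71)
  expect_equal(cv$overall_accuracy, 1)
  expect_identical(sum(cv$per_fold$n_total), 120L)
})

test_that("CV sits at chance for identically distributed classes", {
  set.seed(72)
  X <- matrix(rnorm(400), 200, 2)
  colnames(X) <- c("f1", "f2")
  M <- feature_matrix(X, rep(c("a", "b"), 100),
                      rep(sprintf("s%d", 1:5), 40))
  cv <- cross_validate(M, k_candidates = 1, seed = 72)
  expect_gt(cv$overall_accuracy, 0.35)
  expect_lt(cv$overall_accuracy, 0.65)
})

test_that("label shuffling stays within binomial bounds of chance", {
  set.seed(73)
  X <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 4), 50, 2))
  colnames(X) <- c("f1", "f2")
  labs <- sample(rep(c("a", "b"), 50))   # destroyed signal
  M <- feature_matrix(X, labs, rep(sprintf("s%d", 1:4), 25))
  cv <- cross_validate(M, k_candidates = 1, seed = 73)
  # 99% binomial band around 0.5 at n = 100
  expect_gt(cv$overall_accuracy, 0.5 - 2.58 * 0.05)
  expect_lt(cv$overall_accuracy, 0.5 + 2.58 * 0.05)
})

test_that("folds lacking a class are skipped with a warning", {
  set.seed(74)
  X <- matrix(rnorm(40), 20, 2)
  colnames(X) <- c("f1", "f2")
  labs <- c(rep("a", 5), rep(c("a", "b"), length.out = 15))
  subs <- c(rep("s1", 5), rep(c("s2", "s3"), length.out = 15))
  # remove b from everything except s2/s3; make s2 the only b-holder
  labs[subs == "s3"] <- "a"
  labs[subs == "s2"] <- "b"
  M <- feature_matrix(X, labs, subs)
  expect_warning(cv <- cross_validate(M, k_candidates = 1, seed = 1),
                 "lacks a class")
  expect_identical(cv$skipped_folds, "s2")
})

test_that("our EM attains likelihoods comparable to mclust", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  set.seed(99)
  X <- rbind(matrix(rnorm(300), 150, 2), matrix(rnorm(300, 6), 150, 2))
  ours <- fit_class_gmm(X, 2, seed = 99)
  ref <- suppressWarnings(mclust::Mclust(X, G = 2, modelNames = "VVV",
                                         verbose = FALSE))
  expect_lt(abs(ours$log_likelihood - ref$loglik), 2)
})

test_that("fitted mixtures round-trip through JSON", {
  set.seed(44)
  X <- rbind(matrix(rnorm(200), 100, 2), matrix(rnorm(200, 8), 100, 2))
  colnames(X) <- c("fa", "fb")
  f <- fit_class_gmm(X, 2, seed = 44)
  path <- file.path(tempdir(), "gmm.json")
  write_gmm_json(f, path)
  g <- read_gmm_json(path)
  expect_identical(g$k, f$k)
  expect_equal(g$weights, f$weights, tolerance = 1e-12)
  expect_equal(unname(g$means), unname(f$means), tolerance = 1e-12)
  expect_equal(unname(g$covariances[[1]]), unname(f$covariances[[1]]),
               tolerance = 1e-12)
  expect_identical(g$feature_names, c("fa", "fb"))
  # distances computed from the restored model agree
  expect_equal(classify(X[1, ], list(a = g))$distances,
               classify(X[1, ], list(a = f))$distances, tolerance = 1e-10)
  unlink(path)
})
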