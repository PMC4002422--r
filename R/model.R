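## Gaussian-mixture class models with Mahalanobis-distance classification.
##
## Each image class (e.g. control vs apoptotic) is represented by a full-
## covariance Gaussian mixture fitted by EM; the component count is chosen
## by AIC among candidates (the biological default allows up to 4
## subpopulations per class). A new image is assigned to the class whose
## nearest mixture component is closest in Mahalanobis distance.

#' Mahalanobis distance between a point and a component center
#'
#' `sqrt((x - y)' S^{-1} (x - y))` computed via the Cholesky factor of `S`.
#'
#' @param x,y numeric vectors (point and component mean).
#' @param S symmetric positive-definite covariance matrix.
#' @return Nonnegative scalar distance.
#' @export
mahalanobis_dist <- function(x, y, S) {
  R <- tryCatch(chol(S), error = function(e)
    stop("singular covariance matrix; regularize upstream", call. = FALSE))
  z <- backsolve(R, x - y, transpose = TRUE)
  sqrt(sum(z^2))
}

#' Symmetrized distance between two clusters (or cross-cluster points)
#'
#' The Mahalanobis distance is defined within a single cluster; for a pair
#' of clusters the distance between their centers is computed once under
#' each cluster's covariance and the two values are combined by their
#' arithmetic mean: `(D1 + D2) / 2`.
#'
#' @param c1,c2 lists with elements `mean` and `cov`.
#' @return Nonnegative scalar distance.
#' @export
cross_cluster_distance <- function(c1, c2) {
  d1 <- mahalanobis_dist(c1$mean, c2$mean, c1$cov)
  d2 <- mahalanobis_dist(c1$mean, c2$mean, c2$cov)
  (d1 + d2) / 2
}

# Ridge regularization: add eps to the covariance diagonal, with eps scaled
# to the matrix's own trace and floored at an absolute level so exactly
# degenerate data still yield a PD (scaled-identity) covariance.
ridge_cov <- function(S, ridge = 1e-6, abs_floor = 1e-12) {
  d <- nrow(S)
  eps <- max(ridge * sum(diag(S)) / d, abs_floor)
  S + diag(eps, d)
}

log_mvn_density <- function(X, mean, S) {
  R <- chol(S)
  Ri <- backsolve(R, diag(ncol(X)))
  W <- X %*% Ri
  mw <- as.numeric(rbind(mean) %*% Ri)
  quad <- rowSums((W - rep(mw, each = nrow(X)))^2)
  -0.5 * quad - sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi)
}

# Number of free parameters of a k-component full-covariance mixture in d
# dimensions.
gmm_n_params <- function(k, d) k * (d + d * (d + 1) / 2) + (k - 1)

em_fit_once <- function(X, k, ridge, max_iter = 100, tol = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  if (k == 1) {
    mu <- colMeans(X)
    S <- ridge_cov(crossprod(sweep(X, 2, mu)) / n, ridge)
    ll <- sum(log_mvn_density(X, mu, S))
    return(list(weights = 1, means = matrix(mu, 1), covs = list(S),
                log_likelihood = ll, ok = TRUE))
  }
  km <- tryCatch(suppressWarnings(kmeans(X, centers = k, nstart = 1)),
                 error = function(e) NULL)
  if (is.null(km)) return(list(ok = FALSE))
  z <- km$cluster
  w <- tabulate(z, k) / n
  mu <- km$centers
  covs <- lapply(seq_len(k), function(j) {
    Xj <- X[z == j, , drop = FALSE]
    if (nrow(Xj) < 2)
      return(ridge_cov(diag(apply(X, 2, var), nrow = d), ridge))
    ridge_cov(crossprod(sweep(Xj, 2, colMeans(Xj))) / nrow(Xj), ridge)
  })
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j)
      log(w[j]) + log_mvn_density(X, mu[j, ], covs[[j]]), numeric(n))
    m <- logp[, 1]
    for (j in seq_len(k)[-1]) m <- pmax(m, logp[, j])
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(list(ok = FALSE))
    resp <- exp(logp - lse)
    nk <- colSums(resp)
    # a component supported by fewer effective points than dimensions + 1
    # is collapsing onto a degenerate covariance; reject this restart
    if (any(nk < d + 1)) return(list(ok = FALSE))
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      Xc <- X - rep(mu[j, ], each = n)
      covs[[j]] <- ridge_cov(crossprod(Xc * sqrt(resp[, j])) / nk[j], ridge)
    }
    if (ll - ll_old < tol * (abs(ll_old) + 1) && it > 2) break
    ll_old <- ll
  }
  list(weights = w, means = mu, covs = covs, log_likelihood = ll, ok = TRUE)
}

#' Fit a Gaussian-mixture class model with AIC component selection
#'
#' For each candidate component count an EM fit (full covariances with a
#' trace-scaled ridge, several restarts) is run; the model minimizing
#' `AIC = 2p - 2 log L` is retained. By default `p` is the full mixture
#' parameter count `k (d + d(d+1)/2) + (k - 1)`; `aic_params = "k"` counts
#' only the number of subpopulations.
#'
#' @param X numeric matrix, rows = images of one class, columns = active
#'   features.
#' @param k_candidates integer vector of component counts (default 1:4; up
#'   to 4 subpopulations per class).
#' @param seed integer seed for the EM restarts.
#' @param ridge relative ridge added to covariance diagonals.
#' @param restarts EM restarts per candidate.
#' @param aic_params `"full"` or `"k"` (see above).
#' @return A `gmm_class` list: `k`, `weights`, `means`, `covariances`,
#'   `log_likelihood`, `aic`, `feature_names`.
#' @export
fit_class_gmm <- function(X, k_candidates = 1:4, seed = 1L, ridge = 1e-6,
                          restarts = 5L, aic_params = c("full", "k")) {
  aic_params <- match.arg(aic_params)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  best <- NULL
  for (k in k_candidates) {
    if (k > n) next
    fit_k <- NULL
    for (r in seq_len(if (k == 1) 1L else restarts)) {
      set.seed(seed + 1000L * k + r)
      f <- em_fit_once(X, k, ridge)
      if (f$ok && (is.null(fit_k) || f$log_likelihood > fit_k$log_likelihood))
        fit_k <- f
    }
    if (is.null(fit_k)) next
    p <- if (aic_params == "full") gmm_n_params(k, d) else k
    aic <- 2 * p - 2 * fit_k$log_likelihood
    if (is.null(best) || aic < best$aic) {
      best <- list(k = as.integer(k), weights = fit_k$weights, means = fit_k$means,
                   covariances = fit_k$covs,
                   log_likelihood = fit_k$log_likelihood, aic = aic,
                   feature_names = colnames(X))
    }
  }
  if (is.null(best)) stop("EM failed for every candidate component count")
  class(best) <- "gmm_class"
  best
}

#' Serialize a fitted class mixture as JSON
#'
#' Writes weights, means, covariances, the active feature subset, the
#' component count and the fit criteria; [read_gmm_json()] restores the
#' model.
#'
#' @param gmm a `gmm_class` from [fit_class_gmm()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_gmm_json <- function(gmm, path) {
  out <- list(k = gmm$k, weights = gmm$weights,
              means = apply(gmm$means, 1, identity, simplify = FALSE),
              covariances = lapply(gmm$covariances, function(S)
                apply(S, 1, identity, simplify = FALSE)),
              log_likelihood = gmm$log_likelihood, aic = gmm$aic,
              feature_names = gmm$feature_names)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gmm_json
#' @export
read_gmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  row_bind <- function(rows)
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  structure(list(k = as.integer(x$k),
                 weights = unlist(x$weights),
                 means = row_bind(x$means),
                 covariances = lapply(x$covariances, row_bind),
                 log_likelihood = x$log_likelihood, aic = x$aic,
                 feature_names = unlist(x$feature_names)),
            class = "gmm_class")
}

#' @export
print.gmm_class <- function(x, ...) {
  cat(sprintf("<gmm_class> k = %d components in %d dims, logL = %.2f, AIC = %.2f\n",
              x$k, ncol(x$means), x$log_likelihood, x$aic))
  invisible(x)
}

# Distance from a point to a fitted class = minimum Mahalanobis distance to
# any mixture component of that class.
class_distance <- function(x, gmm) {
  min(vapply(seq_len(gmm$k), function(j)
    mahalanobis_dist(x, gmm$means[j, ], gmm$covariances[[j]]), numeric(1)))
}

#' Classify a feature vector by minimal Mahalanobis distance
#'
#' The distance to a class is the minimum over its mixture components; the
#' point is assigned to the class attaining the smallest distance, ties
#' broken by lexicographic label order.
#'
#' @param x numeric feature vector (restricted to the models' active
#'   features).
#' @param classes named list of `gmm_class` models.
#' @return A `classification_result`: `assigned_class`, `distances`
#'   (named), `margin` (second-best minus best distance).
#' @export
classify <- function(x, classes) {
  if (length(classes) == 0) stop("empty classes map")
  labs <- sort(names(classes))
  d <- vapply(labs, function(l) class_distance(as.numeric(x), classes[[l]]),
              numeric(1))
  i <- which.min(d)      # first index wins: lexicographic tie-break
  structure(list(assigned_class = labs[i], distances = d,
                 margin = if (length(d) > 1) sort(d)[2] - d[i] else Inf),
            class = "classification_result")
}

#' Leave-one-subset-out cross-validation of the GMM classifier
#'
#' Subsets (imaging sessions) are the cross-validation unit: each subset is
#' held out in turn, class mixtures are fitted on the remaining rows, and
#' the held-out rows are classified. A fold whose training data lack one of
#' the classes is skipped with a warning and reported.
#'
#' @param M a [feature_matrix()] (optionally restricted to selected
#'   features).
#' @param k_candidates per-class component candidates for
#'   [fit_class_gmm()].
#' @param seed integer seed.
#' @param features optional character vector of feature names to use.
#' @return A `cv_report`: `per_fold` (data frame), `overall_accuracy`,
#'   `confusion` (table), `skipped_folds`.
#' @export
cross_validate <- function(M, k_candidates = 1:4, seed = 1L, features = NULL) {
  X <- M$X
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  subsets <- sort(unique(M$subset_ids))
  if (length(subsets) < 2) stop("cross-validation needs at least 2 subsets")
  labs <- sort(unique(M$labels))
  conf <- table(factor(character(), labs), factor(character(), labs))
  per_fold <- data.frame(subset = character(), n_correct = integer(),
                         n_total = integer())
  skipped <- character(0)
  for (s in subsets) {
    test <- M$subset_ids == s
    train_labs <- M$labels[!test]
    if (!all(labs %in% train_labs)) {
      warning(sprintf("fold %s skipped: training set lacks a class", s))
      skipped <- c(skipped, s)
      next
    }
    models <- lapply(setNames(labs, labs), function(l)
      fit_class_gmm(X[!test & M$labels == l, , drop = FALSE],
                    k_candidates, seed = seed))
    pred <- vapply(which(test), function(i)
      classify(X[i, ], models)$assigned_class, character(1))
    truth <- M$labels[test]
    conf <- conf + table(factor(truth, labs), factor(pred, labs))
    per_fold <- rbind(per_fold,
                      data.frame(subset = s, n_correct = sum(pred == truth),
                                 n_total = length(truth)))
  }
  if (nrow(per_fold) == 0) stop("all folds were skipped")
  structure(list(per_fold = per_fold,
                 overall_accuracy = sum(per_fold$n_correct) /
                   sum(per_fold$n_total),
                 confusion = conf, skipped_folds = skipped),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> overall accuracy %.3f over %d folds (%d images)\n",
              x$overall_accuracy, nrow(x$per_fold), sum(x$per_fold$n_total)))
  print(x$confusion)
  invisible(x)
}
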