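## Sammon projection to 2D, maximum-variance axis extraction, Texture
## Index computation and center-of-gravity confidence intervals.

#' Pairwise distances between images under class-conditional covariances
#'
#' Within a class the Mahalanobis distance uses that class's covariance;
#' between two points of different classes the distance is computed once
#' under each class's covariance and the two values averaged
#' (see [cross_cluster_distance()]). Class covariances come from a
#' single-Gaussian (ridge-regularized) fit per class unless supplied.
#'
#' With few images per class the per-class covariance is a noisy metric;
#' each class estimate is therefore shrunk toward the pooled within-class
#' covariance (`shrink` = weight of the pooled matrix, default 0.8), a
#' standard small-sample stabilization.
#'
#' @param X numeric matrix of feature rows.
#' @param labels per-row class labels.
#' @param covs optional named list of class covariance matrices (overrides
#'   estimation and shrinkage).
#' @param ridge ridge for the class covariance fits.
#' @param shrink weight in `[0, 1]` of the pooled within-class covariance.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pairwise_class_distances <- function(X, labels, covs = NULL, ridge = 1e-6,
                                     shrink = 0.8) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  labs <- sort(unique(labels))
  if (is.null(covs)) {
    raw <- lapply(setNames(labs, labs), function(l) {
      Xl <- X[labels == l, , drop = FALSE]
      crossprod(sweep(Xl, 2, colMeans(Xl))) / nrow(Xl)
    })
    nl <- vapply(labs, function(l) sum(labels == l), numeric(1))
    pooled <- Reduce(`+`, Map(`*`, raw, nl)) / sum(nl)
    covs <- lapply(raw, function(S)
      ridge_cov((1 - shrink) * S + shrink * pooled, ridge))
  }
  Rinv <- lapply(covs, function(S) backsolve(chol(S), diag(ncol(X))))
  # half-distances under each class metric, computed via whitened coordinates
  W <- lapply(Rinv, function(Ri) X %*% Ri)
  n <- nrow(X)
  D <- matrix(0, n, n)
  euclid <- function(Wm) {
    s <- rowSums(Wm^2)
    d2 <- outer(s, s, `+`) - 2 * tcrossprod(Wm)
    sqrt(pmax(d2, 0))
  }
  Dl <- lapply(W, euclid)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      la <- labels[i]; lb <- labels[j]
      D[i, j] <- D[j, i] <-
        if (la == lb) Dl[[la]][i, j] else (Dl[[la]][i, j] + Dl[[lb]][i, j]) / 2
    }
  }
  D
}

sammon_stress <- function(D, Y, cnorm) {
  dE <- as.matrix(stats::dist(Y))
  iu <- upper.tri(D)
  sum((D[iu] - dE[iu])^2 / D[iu]) / cnorm
}

#' Sammon projection of a distance matrix to 2D
#'
#' Minimizes the Sammon stress
#' `sum_(i<j) (D_ij - d_ij)^2 / D_ij / sum_(i<j) D_ij`
#' by gradient descent with step halving, initialized from classical
#' metric MDS (or a seeded random configuration). The maximum-variance
#' (MVP) and second-variance (SVP) axes are the principal axes of the
#' embedded cloud.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#'   Off-diagonal zeros are floored at 1e-12.
#' @param seed integer seed (used by random initialization).
#' @param max_iter maximal descent iterations.
#' @param tol relative stress-improvement convergence tolerance.
#' @param init `"mds"` (default) or `"random"`.
#' @return A `sammon_embedding`: `points` (n x 2), `stress`, `stress_path`
#'   (non-increasing), `mvp_axis`, `svp_axis`, `iterations_run`.
#' @export
sammon_project <- function(D, seed = 1L, max_iter = 500L, tol = 1e-9,
                           init = c("mds", "random")) {
  init <- match.arg(init)
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be nonnegative")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  D[D == 0] <- 1e-12
  diag(D) <- 0

  if (init == "mds") {
    Y <- suppressWarnings(cmdscale(D, k = 2))
    if (ncol(Y) < 2) {
      set.seed(seed)
      Y <- cbind(Y, rnorm(n, sd = 1e-6 + sd(Y[, 1]) * 1e-6))
    }
  } else {
    set.seed(seed)
    Y <- matrix(rnorm(2 * n, sd = mean(D[upper.tri(D)])), n, 2)
  }

  iu <- upper.tri(D)
  cnorm <- sum(D[iu])
  stress <- sammon_stress(D, Y, cnorm)
  path <- stress
  step <- 0.25
  iters <- 0L
  for (it in seq_len(max_iter)) {
    dE <- as.matrix(stats::dist(Y))
    dE[dE < 1e-12] <- 1e-12
    W <- (D - dE) / (D * dE)
    diag(W) <- 0
    G <- matrix(0, n, 2)
    G[, 1] <- -2 / cnorm * (rowSums(W) * Y[, 1] - W %*% Y[, 1])
    G[, 2] <- -2 / cnorm * (rowSums(W) * Y[, 2] - W %*% Y[, 2])
    gn <- sqrt(sum(G^2))
    if (gn < 1e-18) break
    scale <- mean(dE[iu]) / gn
    improved <- FALSE
    a <- step
    for (h in 1:30) {
      Y2 <- Y - a * scale * G
      s2 <- sammon_stress(D, Y2, cnorm)
      if (s2 < stress) { improved <- TRUE; break }
      a <- a / 2
    }
    if (!improved) break
    Y <- Y2
    iters <- it
    conv <- (stress - s2) < tol * max(stress, 1e-30)
    stress <- s2
    path <- c(path, stress)
    step <- min(a * 1.5, 1)
    if (conv) break
  }

  Yc <- sweep(Y, 2, colMeans(Y))
  eg <- eigen(crossprod(Yc) / max(1, n - 1), symmetric = TRUE)
  structure(list(points = Y, stress = stress, stress_path = path,
                 mvp_axis = eg$vectors[, 1], svp_axis = eg$vectors[, 2],
                 variances = eg$values, iterations_run = iters),
            class = "sammon_embedding")
}

#' @export
print.sammon_embedding <- function(x, ...) {
  cat(sprintf("<sammon_embedding> %d points, stress %.3g after %d iterations\n",
              nrow(x$points), x$stress, x$iterations_run))
  invisible(x)
}

mvp_coords <- function(embedding) {
  as.numeric(sweep(embedding$points, 2, colMeans(embedding$points)) %*%
               embedding$mvp_axis)
}

#' Texture Index between two groups of embedded images
#'
#' The Texture Index (TI) is the displacement of the query group's center
#' from the reference group's center along the maximum-variance (MVP) axis
#' of the embedding.
#'
#' @param embedding a `sammon_embedding`.
#' @param reference_rows,query_rows row indices of the two groups.
#' @param orient +1 or -1 sign convention (callers orient series so the
#'   final timepoint is nonnegative).
#' @return Scalar TI.
#' @export
texture_index <- function(embedding, reference_rows, query_rows, orient = 1) {
  if (length(reference_rows) == 0 || length(query_rows) == 0)
    stop("reference and query row sets must be nonempty")
  mv <- mvp_coords(embedding)
  orient * (mean(mv[query_rows]) - mean(mv[reference_rows]))
}

#' Center of gravity with a normal-theory confidence interval
#'
#' Returns `mean` and halfwidth `Z * s / sqrt(N)` where Z is the upper
#' critical value of the standard normal at the given level (1.96 at 95%)
#' and s the sample standard deviation.
#'
#' @param distances numeric vector (N >= 2).
#' @param level confidence level (default 0.95).
#' @return Named vector `c(mean, halfwidth)`.
#' @export
cog_with_ci <- function(distances, level = 0.95) {
  n <- length(distances)
  if (n < 2) stop("need at least 2 points for a confidence interval")
  z <- qnorm((1 + level) / 2)
  c(mean = mean(distances), halfwidth = z * sd(distances) / sqrt(n))
}

#' Texture Index time series with confidence intervals and t-tests
#'
#' For each timepoint the TI relative to the reference timepoint is
#' computed along the MVP axis, with a normal-theory confidence interval
#' over that timepoint's per-image MVP coordinates and a Welch two-sample
#' t-test against the reference. The TI sign is oriented so the final
#' timepoint is nonnegative.
#'
#' @param embedding a `sammon_embedding` of all images.
#' @param timepoints per-image timepoint values (ordered factor or
#'   numeric).
#' @param reference the reference timepoint (default: the smallest).
#' @param level confidence level for the intervals.
#' @return A `ti_series` data frame: `timepoint`, `n`, `ti`,
#'   `ci_halfwidth`, `p_value` (Welch t-test vs reference; NA for the
#'   reference itself), plus attribute `orient`.
#' @export
ti_series <- function(embedding, timepoints, reference = NULL,
                      level = 0.95) {
  tp <- sort(unique(timepoints))
  if (is.null(reference)) reference <- tp[1]
  mv <- mvp_coords(embedding)
  ref_rows <- which(timepoints == reference)
  z <- qnorm((1 + level) / 2)
  raw <- vapply(tp, function(t) {
    rows <- which(timepoints == t)
    mean(mv[rows]) - mean(mv[ref_rows])
  }, numeric(1))
  orient <- if (raw[length(raw)] >= 0) 1 else -1
  out <- data.frame(
    timepoint = tp,
    n = vapply(tp, function(t) sum(timepoints == t), integer(1)),
    ti = orient * raw,
    ci_halfwidth = vapply(tp, function(t) {
      rows <- which(timepoints == t)
      if (length(rows) < 2) return(NA_real_)
      z * sd(mv[rows]) / sqrt(length(rows))
    }, numeric(1)),
    p_value = vapply(tp, function(t) {
      if (identical(t, reference)) return(NA_real_)
      rows <- which(timepoints == t)
      if (length(rows) < 2 || length(ref_rows) < 2) return(NA_real_)
      t.test(mv[rows], mv[ref_rows])$p.value
    }, numeric(1)))
  attr(out, "orient") <- orient
  class(out) <- c("ti_series", "data.frame")
  out
}
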