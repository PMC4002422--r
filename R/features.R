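## The 65-feature speckle texture parameterization.
##
## Registry order (group sizes 12 + 2 + 12 + 21 + 18 = 65):
##   local_stats[12]   per-voxel entropy/range/sd maps, each summarized by
##                     mean, median, entropy, sd across the ROI
##   moments[2]        skewness, kurtosis of the in-ROI intensities
##   cooccurrence[12]  offset-5 GLCMs along x, y, z; contrast, correlation,
##                     energy, homogeneity each
##   granulometry[21]  12/6/3-bin particle-size histograms of the binarized
##                     ROI
##   wavelet[18]       directional complex wavelet magnitudes along x, y and
##                     the 45-degree diagonal, 3 smallest scales, mean + sd

registry_env <- new.env(parent = emptyenv())

#' The canonical 65-feature registry
#'
#' @return A data frame with columns `name`, `group` and `definition`, in
#'   canonical order. Group sizes are 12 (local_stats), 2 (moments),
#'   12 (cooccurrence), 21 (granulometry) and 18 (wavelet).
#' @export
feature_registry <- function() {
  if (!is.null(registry_env$registry)) return(registry_env$registry)
  maps <- c("entropy", "range", "sd")
  stats <- c("mean", "median", "entropy", "sd")
  ls_names <- as.vector(t(outer(maps, stats, paste, sep = "_")))
  reg <- rbind(
    data.frame(name = paste0("ls_", ls_names), group = "local_stats",
               definition = paste0("ROI ", rep(stats, 3), " of the local ",
                                   rep(maps, each = 4),
                                   " map (normalized by bit depth)")),
    data.frame(name = c("mom_skewness", "mom_kurtosis"), group = "moments",
               definition = c("standardized 3rd central moment of in-ROI intensity",
                              "standardized 4th central moment of in-ROI intensity")),
    data.frame(name = as.vector(t(outer(c("x", "y", "z"),
                                        c("contrast", "correlation",
                                          "energy", "homogeneity"),
                                        function(a, s) paste0("cooc_", a, "_", s)))),
               group = "cooccurrence",
               definition = paste0("offset-5 co-occurrence ",
                                   rep(c("contrast", "correlation", "energy",
                                         "homogeneity"), 3),
                                   " along ", rep(c("x", "y", "z"), each = 4))),
    data.frame(name = c(sprintf("gran12_b%02d", 1:12),
                        sprintf("gran6_b%02d", 1:6),
                        sprintf("gran3_b%02d", 1:3)),
               group = "granulometry",
               definition = c(sprintf("12-bin particle-size fraction, bin %d", 1:12),
                              sprintf("6-bin (pairwise-summed) fraction, bin %d", 1:6),
                              sprintf("3-bin (pairwise-summed) fraction, bin %d", 1:3))),
    data.frame(name = as.vector(vapply(c("x", "y", "diag"), function(d)
                 as.vector(vapply(1:3, function(s)
                   sprintf("wav_%s_s%d_%s", d, s, c("mean", "sd")),
                   character(2))), character(6))),
               group = "wavelet",
               definition = as.vector(vapply(c("x", "y", "45-degree"), function(d)
                 as.vector(vapply(1:3, function(s)
                   sprintf("%s of |coefficients|, %s direction, scale %d",
                           c("mean", "sd"), d, s), character(2))), character(6)))))
  sizes <- table(factor(reg$group, levels = c("local_stats", "moments",
                                              "cooccurrence", "granulometry",
                                              "wavelet")))
  stopifnot(identical(as.integer(sizes), c(12L, 2L, 12L, 21L, 18L)),
            nrow(reg) == 65L, !anyDuplicated(reg$name))
  registry_env$registry <- reg
  reg
}

roi_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ROI is empty")
  apply(idx, 2, range)
}

crop_to_bbox <- function(arr, bb, pad = 0L) {
  d <- dim(arr)
  lo <- pmax(bb[1, ] - pad, 1L)
  hi <- pmin(bb[2, ] + pad, d)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

#' Local-statistics features (12)
#'
#' Three per-voxel maps over sliding cubic neighborhoods — Shannon entropy
#' (half-width `r_ent`, default 5^3 window), intensity range and standard
#' deviation (half-width `r_small`, default 3^3 window) — are computed over
#' the ROI bounding box and summarized across in-ROI voxels by mean, median,
#' entropy and standard deviation. Following the gray-scale-resolution
#' normalization rule, each map is first scaled to the unit range (entropy
#' divided by the bit depth, range by `2^bit_depth - 1`, standard deviation
#' multiplied by `2 / 2^bit_depth`); the summary entropy is again divided by
#' the bit depth and the summary standard deviation multiplied by 2.
#'
#' @param stack an [image_stack()].
#' @param roi a `roi_mask`.
#' @param r_small half-width of the range/sd window.
#' @param r_ent half-width of the entropy window.
#' @return Named numeric vector of 12 features.
#' @export
local_stat_features <- function(stack, roi, r_small = 1L, r_ent = 2L) {
  bb <- roi_bbox(roi$mask)
  ext <- bb[2, ] - bb[1, ] + 1L
  if (any(ext < 2L * r_ent + 1L))
    stop("ROI is smaller than the local neighborhood")
  bd <- stack$bit_depth
  sub <- crop_to_bbox(stack$voxels, bb, pad = r_ent)
  msk <- crop_to_bbox(roi$mask, bb, pad = r_ent)
  maps <- cpp_local_stat_maps(as.integer(sub), dim(sub),
                              r_small, r_ent, 2L^bd)
  inroi <- which(msk)
  norm <- list(entropy = maps$entropy[inroi] / bd,
               range = maps$range[inroi] / (2^bd - 1),
               sd = maps$sd[inroi] * 2 / 2^bd)
  summarize <- function(x) {
    h <- tabulate(pmin(floor(x * 2^bd), 2^bd - 1) + 1L, nbins = 2L^bd)
    p <- h[h > 0] / length(x)
    c(mean = mean(x), median = median(x),
      entropy = -sum(p * log2(p)) / bd,
      sd = if (length(x) > 1) 2 * sd(x) else 0)
  }
  out <- unlist(lapply(norm, summarize))
  names(out) <- feature_registry()$name[1:12]
  out
}

#' Intensity-moment features (2)
#'
#' Standardized third (skewness) and fourth (kurtosis) central moments of
#' the in-ROI intensity distribution, using population central moments.
#' A zero-variance ROI returns `(0, 0)` with a warning.
#'
#' @inheritParams local_stat_features
#' @return Named numeric vector of 2 features.
#' @export
moment_features <- function(stack, roi) {
  x <- as.numeric(stack$voxels[roi$mask])
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) {
    warning("zero in-ROI variance; moments set to (0, 0) by convention")
    out <- c(0, 0)
  } else {
    out <- c(mean((x - m)^3) / m2^1.5, mean((x - m)^4) / m2^2)
  }
  names(out) <- c("mom_skewness", "mom_kurtosis")
  out
}

#' Gray-level co-occurrence features (12)
#'
#' Intensities are quantized into `levels` equal-width gray levels over the
#' full quantization range. For each axis (x, y, z) a co-occurrence matrix
#' with a +`offset_vox` step is accumulated over voxel pairs whose both
#' endpoints lie in the ROI, symmetrized and normalized to sum 1; contrast,
#' correlation, energy and homogeneity are computed from each. The
#' correlation of a degenerate (single-level) matrix is 1 by convention.
#'
#' @inheritParams local_stat_features
#' @param offset_vox pair offset in voxels (default 5, roughly one cell).
#' @param levels number of gray levels (default 8).
#' @return Named numeric vector of 12 features (axis-major: x, y, z).
#' @export
cooccurrence_features <- function(stack, roi, offset_vox = 5L, levels = 8L) {
  bb <- roi_bbox(roi$mask)
  bd <- stack$bit_depth
  sub <- crop_to_bbox(stack$voxels, bb)
  msk <- crop_to_bbox(roi$mask, bb)
  q <- array(pmin(floor(as.numeric(sub) / 2^bd * levels), levels - 1L),
             dim = dim(sub))
  axes <- c(x = 2L, y = 1L, z = 0L)   # cpp axis codes for (z,y,x) arrays
  out <- numeric(0)
  for (a in c("x", "y", "z")) {
    C <- cpp_glcm(as.integer(q), as.logical(msk), dim(sub),
                  as.integer(offset_vox), axes[[a]], as.integer(levels))
    P <- C + t(C)
    tot <- sum(P)
    if (tot == 0)
      stop(sprintf("no valid co-occurrence pairs along axis %s", a),
           call. = FALSE)
    P <- P / tot
    i <- row(P) - 1; j <- col(P) - 1
    pi_ <- rowSums(P)
    mu <- sum((0:(levels - 1)) * pi_)
    s2 <- sum(((0:(levels - 1)) - mu)^2 * pi_)
    corr <- if (s2 <= 0) 1 else sum(P * (i - mu) * (j - mu)) / s2
    out <- c(out, contrast = sum(P * (i - j)^2), correlation = corr,
             energy = sum(P^2), homogeneity = sum(P / (1 + abs(i - j))))
  }
  names(out) <- feature_registry()$name[15:26]
  out
}

#' Binary granulometry features (21)
#'
#' In-ROI voxels are binarized with an Otsu threshold on the in-ROI
#' histogram; below-threshold ("black") voxels are labeled by 26-connected
#' components within the ROI and the particle sizes (voxel counts) are
#' histogrammed into 12 geometric bins, then pairwise-summed into 6 and 3
#' bins. All 21 counts are normalized by the total particle count (zeros
#' when no particles exist).
#'
#' @inheritParams local_stat_features
#' @param bin_edges 13 increasing particle-size bounds; the last bin absorbs
#'   larger particles. Default: powers of two from 1 to 4096 voxels.
#' @return Named numeric vector of 21 features.
#' @export
granulometry_features <- function(stack, roi, bin_edges = 2^(0:12)) {
  if (length(bin_edges) != 13L || is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be 13 strictly increasing particle-size bounds")
  bb <- roi_bbox(roi$mask)
  sub <- crop_to_bbox(stack$voxels, bb)
  msk <- crop_to_bbox(roi$mask, bb)
  thr <- otsu_threshold(as.integer(sub[msk]), stack$bit_depth)
  black <- array(sub <= thr, dim = dim(sub)) & msk
  h12 <- numeric(12)
  if (any(black)) {
    lab <- cpp_label3d(as.logical(black), dim(sub), 26L)
    sizes <- tabulate(lab[lab > 0L])
    sizes <- sizes[sizes > 0L]
    bin <- pmin(pmax(findInterval(sizes, bin_edges), 1L), 12L)
    h12 <- tabulate(bin, nbins = 12L) / length(sizes)
  }
  h6 <- h12[c(TRUE, FALSE)] + h12[c(FALSE, TRUE)]
  h3 <- h6[c(TRUE, FALSE)] + h6[c(FALSE, TRUE)]
  out <- c(h12, h6, h3)
  names(out) <- feature_registry()$name[27:47]
  out
}

#' Directional complex wavelet features (18)
#'
#' Each en-face (y-x) slice intersecting the ROI is filtered with an
#' oriented complex wavelet bank: log-Gabor radial profiles at the three
#' smallest dyadic scales (wavelengths 4, 8 and 16 voxels) times a Gaussian
#' angular window (sigma 22.5 degrees) around the x and y directions and
#' the diagonal (the 45- and 135-degree lobes pooled, so a 90-degree
#' rotation maps the bank onto itself), each restricted to its analytic
#' half-plane so the magnitude is a smooth envelope. Coefficient magnitudes at in-ROI voxels are pooled over
#' slices and summarized per direction and scale by mean and standard
#' deviation. Slices are cropped to the padded ROI bounding box, which makes
#' the features invariant to whole-voxel translations away from the stack
#' border.
#'
#' @inheritParams local_stat_features
#' @param n_scales number of dyadic scales (default 3).
#' @return Named numeric vector of `3 * n_scales * 2` features (18 for the
#'   default).
#' @export
wavelet_features <- function(stack, roi, n_scales = 3L) {
  bb <- roi_bbox(roi$mask)
  ext <- bb[2, ] - bb[1, ] + 1L
  if (any(ext[2:3] < 2^n_scales))
    stop("in-plane ROI extent is too small for the requested scales")
  pad <- 8L
  sub <- crop_to_bbox(stack$voxels, bb, pad = pad)
  msk <- crop_to_bbox(roi$mask, bb, pad = pad)
  # keep only slices that intersect the ROI
  zin <- which(apply(msk, 1, any))
  sub <- sub[zin, , , drop = FALSE]
  msk <- msk[zin, , , drop = FALSE]
  d <- dim(sub)
  bank <- wavelet_filter_bank(d[2], d[3], n_scales)

  # batched 2D FFT of all slices at once
  F3 <- fft_along(fft_along(array(as.numeric(sub), d), 2L), 3L)

  out <- numeric(0)
  npix <- d[2] * d[3]
  inroi <- which(msk)
  for (dir in 1:3) for (s in seq_len(n_scales)) {
    G3 <- aperm(array(bank[[dir]][[s]], c(d[2], d[3], d[1])), c(3, 1, 2))
    coef <- fft_along(fft_along(F3 * G3, 2L, TRUE), 3L, TRUE) / npix
    mg <- Mod(coef)[inroi]
    mu <- mean(mg)
    out <- c(out, mu, if (length(mg) > 1) sd(mg) else 0)
  }
  names(out) <- feature_registry()$name[48:65]
  out
}

# Oriented complex wavelet filters in the frequency domain for an ny x nx
# slice: bank[[dir]][[scale]], dir 1 = x, 2 = y, 3 = diagonal.
wavelet_filter_bank <- function(ny, nx, n_scales = 3L, sigma_theta = pi / 8,
                                sigma_r = 0.65) {
  fy <- (0:(ny - 1)) / ny; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (0:(nx - 1)) / nx; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  FY <- matrix(fy, ny, nx)
  FX <- matrix(fx, ny, nx, byrow = TRUE)
  r <- sqrt(FY^2 + FX^2)
  theta <- atan2(FY, FX)
  lobe <- function(th0) {
    dth <- ((theta - th0 + pi / 2) %% pi) - pi / 2
    exp(-dth^2 / (2 * sigma_theta^2)) * (cos(theta - th0) > 0)
  }
  # the diagonal channel pools the 45 and 135 degree lobes so that a
  # 90-degree rotation maps the bank onto itself exactly
  angs <- list(x = lobe(0), y = lobe(pi / 2),
               diag = lobe(pi / 4) + lobe(3 * pi / 4))
  lapply(angs, function(ang) {
    lapply(seq_len(n_scales), function(s) {
      f0 <- 1 / (4 * 2^(s - 1))
      rad <- ifelse(r > 0, exp(-(log(pmax(r, 1e-12) / f0))^2 /
                                 (2 * log(sigma_r)^2)), 0)
      rad * ang
    })
  })
}

#' Extract the full 65-feature vector of an ROI
#'
#' Concatenates the five families in registry order: local statistics (12),
#' moments (2), co-occurrence (12), granulometry (21), wavelet (18).
#'
#' @inheritParams local_stat_features
#' @param config optional named list overriding family parameters:
#'   `r_small`, `r_ent`, `cooc_offset`, `cooc_levels`, `gran_edges`,
#'   `n_scales`.
#' @return A named numeric vector of exactly 65 finite values, with
#'   attribute `bit_depth_used`.
#' @export
extract_features <- function(stack, roi, config = list()) {
  cfg <- modifyList(list(r_small = 1L, r_ent = 2L, cooc_offset = 5L,
                         cooc_levels = 8L, gran_edges = 2^(0:12),
                         n_scales = 3L), config)
  out <- c(local_stat_features(stack, roi, cfg$r_small, cfg$r_ent),
           moment_features(stack, roi),
           cooccurrence_features(stack, roi, cfg$cooc_offset, cfg$cooc_levels),
           granulometry_features(stack, roi, cfg$gran_edges),
           wavelet_features(stack, roi, cfg$n_scales))
  stopifnot(identical(names(out), feature_registry()$name),
            all(is.finite(out)))
  attr(out, "bit_depth_used") <- stack$bit_depth
  out
}

#' Assemble a feature matrix from per-ROI feature vectors
#'
#' @param vectors list of vectors from [extract_features()].
#' @param labels per-row class labels.
#' @param subset_ids per-row imaging-session subset ids (nonempty strings).
#' @param timepoints optional per-row numeric timepoints.
#' @return A `feature_matrix`: list with `X` (rows = ROIs, columns = the 65
#'   registry features), `labels`, `subset_ids`, `timepoints`.
#' @export
feature_matrix <- function(vectors, labels, subset_ids, timepoints = NULL) {
  if (is.matrix(vectors)) {
    X <- vectors
  } else {
    nms <- names(vectors[[1]])
    X <- do.call(rbind, lapply(vectors, as.numeric))
    colnames(X) <- if (!is.null(nms)) nms else feature_registry()$name
  }
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  labels <- as.character(labels)
  subset_ids <- as.character(subset_ids)
  if (length(labels) != n || length(subset_ids) != n)
    stop("labels and subset_ids must match the number of rows")
  if (any(!nzchar(subset_ids))) stop("subset_ids must be nonempty strings")
  if (!is.null(timepoints) && length(timepoints) != n)
    stop("timepoints must match the number of rows")
  structure(list(X = X, labels = labels, subset_ids = subset_ids,
                 timepoints = timepoints), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d ROIs x %d features; classes: %s; %d subsets\n",
              nrow(x$X), ncol(x$X),
              paste(unique(x$labels), collapse = ", "),
              length(unique(x$subset_ids))))
  invisible(x)
}

#' Write the feature registry as a JSON reference file
#'
#' Documents every feature's name, group and definition.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a feature matrix as CSV
#'
#' One row per ROI; the 65 canonical feature columns followed by `label`,
#' `subset_id` and (when present) `timepoint`.
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `path` invisibly, or the `feature_matrix` for the reader.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$X)
  df$label <- fm$labels
  df$subset_id <- fm$subset_ids
  if (!is.null(fm$timepoints)) df$timepoint <- fm$timepoints
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  feats <- feature_registry()$name
  feature_matrix(lapply(seq_len(nrow(df)), function(i)
    as.numeric(df[i, feats])),
    df$label, df$subset_id,
    if ("timepoint" %in% names(df)) df$timepoint else NULL)
}
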