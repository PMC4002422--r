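#' Otsu threshold of an intensity sample
#'
#' Classic between-class-variance maximization on the histogram of integer
#' intensities in `[0, 2^bit_depth - 1]`. Returns the threshold level t such
#' that `value > t` is foreground.
#'
#' @param values integer intensities.
#' @param bit_depth quantization bit depth.
#' @return The threshold (a level in `[0, 2^bit_depth - 2]`).
#' @export
otsu_threshold <- function(values, bit_depth = 8L) {
  L <- 2^bit_depth
  h <- as.numeric(tabulate(values + 1L, nbins = L))
  n <- sum(h)
  if (n == 0) stop("empty intensity sample")
  lev <- 0:(L - 1)
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mt <- m0[L]
  w1 <- n - w0
  between <- (mt * w0 - n * m0)^2 / (w0 * w1 * n^2)
  between[w0 == 0 | w1 == 0] <- 0
  lev[which.max(between)]
}

# --- binary ball morphology on 3D logical arrays -------------------------

ball_dilate <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  d <- cpp_edt_sq(as.logical(mask), dim(mask))
  out <- array(d <= radius^2 + 1e-9, dim = dim(mask))
  out
}

ball_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- cpp_edt_sq(as.logical(!mask), dim(mask))
  array(d > radius^2 + 1e-9, dim = dim(mask)) & mask
}

# Fill background cavities: any background component (6-connectivity) that
# does not touch the volume boundary is absorbed into the mask.
fill_holes3d <- function(mask) {
  bg <- !mask
  lab <- array(cpp_label3d(as.logical(bg), dim(mask), 6L), dim = dim(mask))
  if (max(lab) == 0L) return(mask)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  holes <- setdiff(seq_len(max(lab)), border)
  if (length(holes)) mask[lab %in% holes] <- TRUE
  mask
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- cpp_label3d(as.logical(mask), dim(mask), connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim = dim(mask))
}

new_roi_mask <- function(mask, mode, threshold, closing, erosion) {
  structure(list(mask = mask, mode = mode, threshold_used = threshold,
                 closing_radius_vox = closing, erosion_radius_vox = erosion),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, %d voxels (%.1f%% of volume), threshold %s\n",
              x$mode, sum(x$mask), 100 * mean(x$mask),
              format(x$threshold_used)))
  invisible(x)
}

#' Automatically mask the cell-bearing region of interest
#'
#' Thresholding (Otsu by default; an explicit level may be given), largest
#' 26-connected component, morphological closing with a discrete ball,
#' cavity filling, then erosion — producing a single homogeneous 3D mask
#' without interior holes.
#'
#' @param stack a preprocessed [image_stack()].
#' @param threshold `"auto"` for Otsu on the stack histogram, or an explicit
#'   intensity level (foreground is strictly above it).
#' @param closing_radius_vox ball radius for morphological closing.
#' @param erosion_radius_vox ball radius for the final erosion.
#' @return A `roi_mask`.
#' @export
mask_roi_auto <- function(stack, threshold = "auto", closing_radius_vox = 5L,
                          erosion_radius_vox = 2L) {
  v <- stack$voxels
  thr <- if (identical(threshold, "auto")) {
    otsu_threshold(as.vector(v), stack$bit_depth)
  } else {
    as.numeric(threshold)
  }
  mask <- array(v > thr, dim = dim(v))
  if (!any(mask)) stop("ROI vanished: nothing above threshold", call. = FALSE)
  mask <- largest_component(mask)
  mask <- ball_erode(ball_dilate(mask, closing_radius_vox), closing_radius_vox)
  mask <- fill_holes3d(mask)
  mask <- ball_erode(mask, erosion_radius_vox)
  # closing/erosion can split off slivers; keep the dominant body
  if (any(mask)) mask <- largest_component(mask)
  if (!any(mask))
    stop("ROI vanished after erosion; use a smaller erosion_radius_vox",
         call. = FALSE)
  new_roi_mask(mask, "automatic", thr, closing_radius_vox, erosion_radius_vox)
}

#' Refine manually seeded ROI boxes
#'
#' Mirrors the explant workflow: boxes (e.g. hand-picked within the inner
#' plexiform layer) are refined independently by running the automatic
#' masking restricted to each box. Returned masks are full-volume arrays
#' (TRUE only inside the refined box region) and may overlap; no
#' deduplication is performed.
#'
#' @param stack a preprocessed [image_stack()].
#' @param seed_boxes list of boxes, each a list/vector with 0-based
#'   half-open bounds `z0, z1, y0, y1, x0, x1`.
#' @param ... passed to [mask_roi_auto()].
#' @return A list of `roi_mask` objects (mode `"manual_seed"`).
#' @export
mask_roi_manual <- function(stack, seed_boxes, ...) {
  d <- dim(stack$voxels)
  lapply(seq_along(seed_boxes), function(i) {
    b <- as.list(seed_boxes[[i]])
    need <- c("z0", "z1", "y0", "y1", "x0", "x1")
    if (!all(need %in% names(b)))
      stop(sprintf("seed box %d: missing bounds", i), call. = FALSE)
    b <- lapply(b, as.integer)
    if (b$z0 < 0 || b$y0 < 0 || b$x0 < 0 ||
        b$z1 > d[1] || b$y1 > d[2] || b$x1 > d[3] ||
        b$z0 >= b$z1 || b$y0 >= b$y1 || b$x0 >= b$x1)
      stop(sprintf("seed box %d is out of bounds for a %s stack",
                   i, paste(d, collapse = "x")), call. = FALSE)
    sub <- image_stack(
      stack$voxels[(b$z0 + 1):b$z1, (b$y0 + 1):b$y1, (b$x0 + 1):b$x1,
                   drop = FALSE],
      stack$voxel_pitch_um, stack$bit_depth, stack$metadata)
    r <- mask_roi_auto(sub, ...)
    full <- array(FALSE, dim = d)
    full[(b$z0 + 1):b$z1, (b$y0 + 1):b$y1, (b$x0 + 1):b$x1] <- r$mask
    new_roi_mask(full, "manual_seed", r$threshold_used,
                 r$closing_radius_vox, r$erosion_radius_vox)
  })
}

#' Read seed boxes from a JSON file
#'
#' Expects an array of objects with 0-based half-open bounds
#' `{"z0":..,"z1":..,"y0":..,"y1":..,"x0":..,"x1":..}`.
#' @param path JSON path.
#' @return A list of boxes for [mask_roi_manual()].
#' @export
read_seed_boxes <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

#' Histogram equalization restricted to the ROI
#'
#' Brightness variation inside the ROI (largely a depth-of-focus effect) is
#' flattened by mapping in-ROI intensities through their empirical CDF onto
#' the full quantization range. Out-of-ROI voxels are untouched. Idempotent
#' up to quantization.
#'
#' @param stack an [image_stack()].
#' @param roi a `roi_mask`.
#' @return The equalized [image_stack()].
#' @export
equalize_in_roi <- function(stack, roi) {
  if (!any(roi$mask)) stop("ROI is empty")
  v <- stack$voxels
  L <- 2^stack$bit_depth
  vals <- v[roi$mask]
  h <- tabulate(vals + 1L, nbins = L)
  cdf <- cumsum(h) / length(vals)
  map <- round(cdf * (L - 1))
  out <- v
  out[roi$mask] <- map[vals + 1L]
  with_voxels(stack, out)
}

#' Write an ROI mask as an 8-bit multi-page TIFF (0/255)
#'
#' @param roi a `roi_mask`.
#' @param stack the [image_stack()] the mask belongs to (for geometry).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_roi_tiff <- function(roi, stack, path) {
  m <- image_stack(array(255 * roi$mask, dim = dim(roi$mask)),
                   stack$voxel_pitch_um, 8L,
                   metadata = list(mode = roi$mode))
  write_stack_tiff(m, path)
}
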