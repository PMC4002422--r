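#' Construct an OCT image stack
#'
#' An `image_stack` is the package's container for a 3D grayscale volume:
#' an integer intensity array in `(z, y, x)` order (z = depth/axial axis),
#' a transverse voxel pitch in micrometers, the quantization bit depth, and
#' free-form string metadata (timepoint, group label, subset id, ...).
#'
#' @param voxels 3D numeric array in `(z, y, x)` order. Values are rounded
#'   and clipped to `[0, 2^bit_depth - 1]`.
#' @param voxel_pitch_um transverse voxel pitch in micrometers.
#' @param bit_depth quantization bit depth (default 8).
#' @param metadata named list of character scalars.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_pitch_um = 1.46, bit_depth = 8L,
                        metadata = list()) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) <= 0L)) stop("voxels dimensions must be positive")
  if (!is.numeric(voxel_pitch_um) || voxel_pitch_um <= 0)
    stop("voxel_pitch_um must be a positive real")
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L) stop("bit_depth must be a positive integer")
  maxlev <- 2^bit_depth - 1
  v <- round(voxels)
  v[v < 0] <- 0
  v[v > maxlev] <- maxlev
  storage.mode(v) <- "integer"
  structure(
    list(voxels = v, voxel_pitch_um = voxel_pitch_um,
         bit_depth = bit_depth, metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), %d-bit, pitch %.2f um\n",
              d[1], d[2], d[3], x$bit_depth, x$voxel_pitch_um))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

max_level <- function(stack) 2^stack$bit_depth - 1L

# FFT of a 3D array along one dimension for all remaining indices at once
# (batched via mvfft). Unnormalized, like stats::fft.
fft_along <- function(a, dimn, inverse = FALSE) {
  dd <- dim(a)
  perm <- c(dimn, setdiff(1:3, dimn))
  m <- matrix(aperm(a, perm), nrow = dd[dimn])
  mf <- stats::mvfft(m, inverse = inverse)
  dim(mf) <- dd[perm]
  aperm(mf, order(perm))
}

#' Replace the voxel array of a stack, preserving geometry and metadata
#'
#' Values are re-quantized (rounded and clipped) to the stack's bit depth.
#' @param stack an `image_stack`.
#' @param voxels replacement array of identical dimensions.
#' @return The updated `image_stack`.
#' @export
with_voxels <- function(stack, voxels) {
  image_stack(voxels, stack$voxel_pitch_um, stack$bit_depth, stack$metadata)
}

#' Write a stack as a multi-page grayscale TIFF with a JSON sidecar
#'
#' One TIFF page per depth slice `z`; intensities are stored at the stack's
#' bit depth. Pitch, bit depth and metadata go to `<path>.json`.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$voxels)
  maxlev <- max_level(stack)
  pages <- lapply(seq_len(d[1]), function(z) {
    m <- stack$voxels[z, , , drop = TRUE]
    matrix(m / maxlev, nrow = d[2], ncol = d[3])
  })
  bps <- if (stack$bit_depth <= 8) 8L else 16L
  tiff::writeTIFF(pages, path, bits.per.sample = bps)
  sidecar <- list(voxel_pitch_um = stack$voxel_pitch_um,
                  bit_depth = stack$bit_depth,
                  dim_zyx = d,
                  metadata = stack$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside.
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2])
  maxlev <- 2^side$bit_depth - 1
  v <- array(0L, dim = d)
  for (z in seq_along(pages)) v[z, , ] <- round(pages[[z]] * maxlev)
  md <- side$metadata
  if (is.null(md)) md <- list()
  image_stack(v, side$voxel_pitch_um, side$bit_depth, as.list(md))
}
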