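#' Clip saturated-reflection streaks
#'
#' Specular reflections saturate the detector over runs of consecutive axial
#' samples. Voxels at the maximum quantization level in at least `run_len`
#' consecutive z positions are replaced by the median of their 3x3x3
#' neighborhood.
#'
#' @param stack an [image_stack()].
#' @param run_len minimal saturated run length (voxels) that marks a
#'   reflection streak.
#' @return The cleaned [image_stack()].
#' @export
remove_reflections <- function(stack, run_len = 5L) {
  v <- stack$voxels
  maxlev <- max_level(stack)
  sat <- v == maxlev
  if (!any(sat)) return(stack)
  d <- dim(v)
  flag <- array(FALSE, dim = d)
  for (x in seq_len(d[3])) {
    sm <- sat[, , x, drop = TRUE]
    hit_col <- which(colSums(sm) >= run_len)
    for (y in hit_col) {
      r <- rle(sm[, y])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= run_len))
        flag[starts[k]:ends[k], y, x] <- TRUE
    }
  }
  if (!any(flag)) return(stack)
  idx <- which(flag, arr.ind = TRUE)
  out <- v
  for (i in seq_len(nrow(idx))) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    zz <- max(1, z - 1):min(d[1], z + 1)
    yy <- max(1, y - 1):min(d[2], y + 1)
    xx <- max(1, x - 1):min(d[3], x + 1)
    out[z, y, x] <- median(v[zz, yy, xx])
  }
  with_voxels(stack, out)
}

# Robust spectral peak detection along one axis line of a 2D FFT.
# amps: magnitudes along the line (index 1 = DC). The local band is a
# 15-bin running window along the line (a narrow peak cannot drag its own
# running median). Returns flagged indices and replacement magnitudes.
notch_line <- function(amps, c_mad = 6, guard = NULL, window = 15L) {
  n <- length(amps)
  # protect the anatomy-scale band: layer spacings and plane profiles live
  # at wavelengths above ~8 voxels, fixed-pattern oscillations well below
  if (is.null(guard)) guard <- max(2L, round(n / 8))
  med <- runmed(amps, min(window, n - (1 - n %% 2)), endrule = "median")
  dev <- 1.4826 * runmed(abs(amps - med),
                         min(window, n - (1 - n %% 2)), endrule = "median")
  fr <- pmin(seq_len(n) - 1L, n - seq_len(n) + 1L)   # distance from DC
  # a peak must exceed the robust threshold AND carry at least twice the
  # band's power, so smooth spectral ripple is never notched
  hit <- which(fr > guard & amps > med + c_mad * dev &
                 amps > sqrt(2) * med & amps > 0)
  list(idx = hit, repl = med[hit])
}

#' Remove fixed-pattern line-scan artifacts by FFT notch filtering
#'
#' Each B-scan (fixed y; a z-by-x image) is Fourier transformed and the two
#' spectral axis lines that carry fixed-pattern structure (the kx = 0 column
#' and the kz = 0 row) are scanned for narrow peaks: a bin is flagged when
#' its magnitude exceeds the median + `c_mad` * MAD of a 15-bin running
#' window along the same axis line and carries at least twice the band's
#' power. Flagged bins have their magnitude set to the median of their
#' 2-8-bin neighbors in every slice, phase preserved. The low-frequency
#' band (within n/8 bins of DC) is never touched: plane profiles and
#' layer spacings live there, while fixed-pattern oscillations sit at
#' higher frequencies. With no detected peaks the operation is the
#' identity up to quantization.
#'
#' Fixed-pattern structure is coherent across B-scans while speckle is not,
#' so peaks are detected on the slice-averaged amplitude spectrum (which
#' suppresses speckle fluctuation by the square root of the slice count)
#' and the flagged bins are then attenuated in every slice.
#'
#' @param stack an [image_stack()].
#' @param c_mad robust threshold multiplier (default 6).
#' @return The filtered [image_stack()]; the number of distinct notched
#'   spectral bins is attached as attribute `n_notched`.
#' @export
remove_line_artifacts <- function(stack, c_mad = 6) {
  v <- stack$voxels
  d <- dim(v)
  F3 <- fft_along(fft_along(array(as.numeric(v), d), 1L), 3L)
  A <- Mod(F3)
  A_col <- rowMeans(A[, , 1, drop = TRUE])    # kx = 0 line, averaged over y
  A_row <- colMeans(A[1, , , drop = TRUE])    # kz = 0 line, averaged over y
  cr <- notch_line(A_col, c_mad = c_mad)
  rr <- notch_line(A_row, c_mad = c_mad)
  if (length(cr$idx) == 0 && length(rr$idx) == 0) {
    attr(stack, "n_notched") <- 0L
    return(stack)
  }
  nb_median <- function(a, i) {
    nb <- c(i - 8:2, i + 2:8)
    nb <- nb[nb >= 1 & nb <= length(a)]
    median(a[nb])
  }
  for (y in seq_len(d[2])) {
    if (length(cr$idx)) {
      a <- Mod(F3[, y, 1])
      for (i in cr$idx) if (a[i] > 0)
        F3[i, y, 1] <- F3[i, y, 1] * nb_median(a, i) / a[i]
    }
    if (length(rr$idx)) {
      a <- Mod(F3[1, y, ])
      for (i in rr$idx) if (a[i] > 0)
        F3[1, y, i] <- F3[1, y, i] * nb_median(a, i) / a[i]
    }
  }
  out <- Re(fft_along(fft_along(F3, 1L, TRUE), 3L, TRUE)) / (d[1] * d[3])
  res <- with_voxels(stack, out)
  attr(res, "n_notched") <- length(cr$idx) + length(rr$idx)
  res
}

#' Detect the coverslip plane
#'
#' The coverslip is the dominant bright planar interface. Its depth is found
#' per transverse position as the peak of the axial gradient magnitude
#' (the high-frequency image component along depth), smoothed transversely
#' (9x9 window) so incoherent speckle gradients average out while the
#' coherent interface survives, and axially (5 samples) so the two flank
#' peaks of the interface profile merge. Peak depths are refined to sub-voxel
#' precision by parabolic interpolation and a plane `z = b0 + b1*(y-yc) +
#' b2*(x-xc)` is fitted by least squares with iterated outlier rejection
#' (3 MAD).
#'
#' @param stack an [image_stack()].
#' @param energy_floor minimal smoothed peak gradient (quantization levels)
#'   for a column to participate in the fit.
#' @return A `coverslip_plane` list: `b0`, `slope_y`, `slope_x`, `normal`
#'   (unit vector in (z,y,x)), `tilt_y_deg`, `tilt_x_deg`, `residual_rms`,
#'   `n_columns_used`.
#' @export
detect_coverslip <- function(stack, energy_floor = 4) {
  v <- stack$voxels
  d <- dim(v)
  g <- abs(v[-1, , , drop = FALSE] - v[-d[1], , , drop = FALSE])
  dg <- dim(g)

  # Smooth the gradient magnitude: 9x9 transversely (incoherent speckle
  # gradients average out, the coherent interface survives) and 5 axially
  # (merges the two flank peaks of the interface profile into one maximum
  # centered on the plane). Edges are replicate-padded.
  runbox <- function(mm, k) {
    n <- nrow(mm)
    h <- k %/% 2
    p <- rbind(mm[rep(1, h), , drop = FALSE], mm,
               mm[rep(n, h), , drop = FALSE])
    f <- stats::filter(p, rep(1 / k, k), sides = 2)
    matrix(f[(h + 1):(n + h), ], nrow = n)
  }
  gs <- array(0, dim = dg)
  for (z in seq_len(dg[1]))
    gs[z, , ] <- t(runbox(t(runbox(g[z, , , drop = TRUE], 9L)), 9L))
  for (x in seq_len(d[3])) gs[, , x] <- runbox(gs[, , x, drop = TRUE], 5L)

  peak_z <- matrix(NA_real_, d[2], d[3])
  peak_e <- matrix(0, d[2], d[3])
  for (x in seq_len(d[3])) {
    col <- gs[, , x, drop = TRUE]           # nz-1 x ny
    iz <- max.col(t(col), ties.method = "first")
    e <- col[cbind(iz, seq_len(d[2]))]
    zc <- iz + 0.5                           # gradient bin between z and z+1
    # parabolic sub-voxel refinement on the smoothed gradient
    ok <- iz > 1 & iz < dg[1]
    if (any(ok)) {
      ym <- col[cbind(pmax(iz - 1, 1), seq_len(d[2]))]
      yp <- col[cbind(pmin(iz + 1, dg[1]), seq_len(d[2]))]
      den <- ym - 2 * e + yp
      shift <- ifelse(ok & den < 0, 0.5 * (ym - yp) / den, 0)
      shift[!is.finite(shift)] <- 0
      zc <- zc + pmax(-0.5, pmin(0.5, shift))
    }
    peak_z[, x] <- zc
    peak_e[, x] <- e
  }

  use <- peak_e > energy_floor
  if (sum(use) < 8)
    stop("no coverslip found: no transverse column exceeds the ",
         "high-frequency energy floor", call. = FALSE)

  yc <- (d[2] + 1) / 2; xc <- (d[3] + 1) / 2
  yy <- matrix(seq_len(d[2]) - yc, d[2], d[3])
  xx <- matrix(seq_len(d[3]) - xc, d[2], d[3], byrow = TRUE)
  sel <- which(use)
  for (it in 1:3) {
    X <- cbind(1, yy[sel], xx[sel])
    b <- qr.solve(X, peak_z[sel])
    res <- peak_z[sel] - X %*% b
    s <- mad(res)
    keep <- abs(res) <= max(3 * s, 1)
    if (all(keep)) break
    sel <- sel[keep]
    if (length(sel) < 8) break
  }
  X <- cbind(1, yy[sel], xx[sel])
  b <- qr.solve(X, peak_z[sel])
  res <- peak_z[sel] - X %*% b

  nrm <- c(1, -b[2], -b[3])
  nrm <- nrm / sqrt(sum(nrm^2))
  structure(list(b0 = unname(b[1]), slope_y = unname(b[2]),
                 slope_x = unname(b[3]), normal = nrm,
                 tilt_y_deg = atan(b[2]) * 180 / pi,
                 tilt_x_deg = atan(b[3]) * 180 / pi,
                 residual_rms = sqrt(mean(res^2)),
                 n_columns_used = length(sel)),
            class = "coverslip_plane")
}

#' Remove coverslip tilt by axial realignment
#'
#' Every transverse column is shifted along z (sub-voxel, linear
#' interpolation) so the detected plane becomes axis-aligned at depth `b0`.
#' Out-of-domain voxels are set to 0 and intensities are re-quantized to
#' the original bit depth; output dimensions equal input dimensions. For
#' the small tilts in scope (< 30 degrees) axial shear agrees with a rigid
#' rotation to first order and inverts a plane tilt exactly.
#'
#' @param stack an [image_stack()].
#' @param plane a `coverslip_plane` from [detect_coverslip()], or any list
#'   with `b0`, `slope_y`, `slope_x`.
#' @param max_tilt_deg refuse tilts beyond this angle.
#' @return The realigned [image_stack()].
#' @export
remove_tilt <- function(stack, plane, max_tilt_deg = 30) {
  tilts <- atan(c(plane$slope_y, plane$slope_x)) * 180 / pi
  if (any(abs(tilts) > max_tilt_deg))
    stop(sprintf("tilt of %.1f degrees exceeds the %g degree limit",
                 max(abs(tilts)), max_tilt_deg), call. = FALSE)
  if (plane$slope_y == 0 && plane$slope_x == 0) return(stack)
  v <- stack$voxels
  d <- dim(v)
  yc <- (d[2] + 1) / 2; xc <- (d[3] + 1) / 2
  zs <- seq_len(d[1])
  out <- array(0, dim = d)
  for (x in seq_len(d[3])) {
    sh <- plane$slope_y * (seq_len(d[2]) - yc) + plane$slope_x * (x - xc)
    src <- outer(zs, sh, `+`)               # nz x ny source depths
    lo <- floor(src)
    w <- src - lo
    m <- matrix(as.numeric(v[, , x]), nrow = d[1])
    val_at <- function(zi) {
      ok <- zi >= 1 & zi <= d[1]
      zi2 <- pmin(pmax(zi, 1), d[1])
      r <- m[cbind(as.vector(zi2), rep(seq_len(d[2]), each = d[1]))]
      r[!ok] <- 0
      matrix(r, nrow = d[1])
    }
    out[, , x] <- (1 - w) * val_at(lo) + w * val_at(lo + 1L)
  }
  with_voxels(stack, out)
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: reflection clipping, FFT line-artifact notching,
#' coverslip detection, tilt removal, then (optionally) cropping to the
#' region below the coverslip. The report records the fitted plane, the
#' applied tilts, the number of notched spectral bins and the crop box
#' (0-based, half-open voxel bounds).
#'
#' @param stack an [image_stack()].
#' @param c_mad notch threshold multiplier, see [remove_line_artifacts()].
#' @param energy_floor see [detect_coverslip()].
#' @param crop_below_coverslip if TRUE, crop z to below the coverslip
#'   (maximum plane depth plus `crop_margin`).
#' @param crop_margin voxels kept clear below the coverslip when cropping.
#' @param detect if FALSE, skip coverslip detection and tilt removal.
#' @return A list with elements `stack` (the preprocessed [image_stack()])
#'   and `report` (a `preprocess_report` list).
#' @export
preprocess_stack <- function(stack, c_mad = 6, energy_floor = 4,
                             crop_below_coverslip = FALSE, crop_margin = 4L,
                             detect = TRUE) {
  d0 <- dim(stack$voxels)
  s <- remove_reflections(stack)
  s <- remove_line_artifacts(s, c_mad = c_mad)
  n_notched <- attr(s, "n_notched")
  attr(s, "n_notched") <- NULL

  plane <- NULL
  tilts <- c(0, 0, 0)
  if (detect) {
    plane <- detect_coverslip(s, energy_floor = energy_floor)
    tilts <- c(plane$tilt_y_deg, plane$tilt_x_deg, 0)
    # tilts below 0.05 degrees shift the farthest voxel by well under the
    # quantization step; treat the stack as already axis-aligned
    if (max(abs(tilts)) >= 0.05) s <- remove_tilt(s, plane)
  }

  crop_box <- rbind(z = c(0L, d0[1]), y = c(0L, d0[2]), x = c(0L, d0[3]))
  if (crop_below_coverslip && !is.null(plane)) {
    z0 <- as.integer(min(d0[1] - 8L, max(1L, ceiling(plane$b0) + crop_margin)))
    s$voxels <- s$voxels[(z0 + 1L):d0[1], , , drop = FALSE]
    crop_box["z", ] <- c(z0, d0[1])
  }
  storage.mode(crop_box) <- "integer"

  report <- structure(
    list(coverslip_plane = plane, applied_tilts_deg = tilts,
         n_artifact_frequencies_notched = n_notched, crop_box = crop_box),
    class = "preprocess_report")
  list(stack = s, report = report)
}

#' Serialize a preprocessing report as JSON
#'
#' @param report a `preprocess_report` from [preprocess_stack()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  pl <- report$coverslip_plane
  out <- list(
    coverslip_plane = if (is.null(pl)) NULL else
      list(b0 = pl$b0, slope_y = pl$slope_y, slope_x = pl$slope_x,
           normal = pl$normal, residual_rms = pl$residual_rms,
           n_columns_used = pl$n_columns_used),
    applied_tilts_deg = report$applied_tilts_deg,
    n_artifact_frequencies_notched = report$n_artifact_frequencies_notched,
    crop_box = apply(report$crop_box, 1, identity, simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
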