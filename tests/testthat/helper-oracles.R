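# Independent oracles and small fixture builders used across the suite.

# Brute-force BFS connected-component labeling of a 3D logical array.
# Deliberately independent of the package's union-find implementation.
bfs_label3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      a <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        z <- a[1] + offs$dz[k]; y <- a[2] + offs$dy[k]; x <- a[3] + offs$dx[k]
        if (z < 1 || y < 1 || x < 1 || z > d[1] || y > d[2] || x > d[3]) next
        i <- z + d[1] * ((y - 1) + d[2] * (x - 1))
        if (mask[i] && lab[i] == 0L) {
          lab[i] <- nextlab
          queue <- c(queue, i)
        }
      }
    }
  }
  lab
}

# Upper-quantile particle size of the binarized slab interior: the
# granulometry drift statistic, computed entirely with the BFS oracle.
oracle_particle_p90 <- function(stack, q = 0.25, connectivity = 6L) {
  tr <- attr(stack, "truth")
  v <- stack$voxels[(tr$active_z[1] + 3):(tr$active_z[2] - 3), , ]
  thr <- quantile(v, q)
  black <- array(v <= thr, dim = dim(v))
  lab <- bfs_label3d(black, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  unname(quantile(sizes[sizes > 0], 0.9))
}

# A uniform bright cuboid on a dark background.
cube_stack <- function(dim3 = c(32L, 32L, 32L), lo = 9L, hi = 24L,
                       value = 200L) {
  v <- array(0L, dim = dim3)
  v[lo:hi, lo:hi, lo:hi] <- value
  image_stack(v)
}

full_roi <- function(stack) {
  speckletex:::new_roi_mask(array(TRUE, dim = dim(stack$voxels)),
                            "automatic", 0, 0L, 0L)
}

roi_from_mask <- function(mask) {
  speckletex:::new_roi_mask(mask, "automatic", 0, 0L, 0L)
}

# A small phantom, fast enough for module-level tests.
quick_phantom <- function(seed = 1L, degeneration = 0, shape = c(48L, 40L, 40L),
                          ...) {
  generate_phantom(phantom_spec(shape = shape, degeneration = degeneration,
                                seed = seed, ...))
}

# Fixed-pattern peak power at one kz bin of the kx = 0 spectral line,
# relative to the local band median, measured on the slice-averaged
# amplitude spectrum (direct FFT power measurement at the injected
# frequency; averaging over B-scans suppresses speckle fluctuation).
avg_peak_ratio <- function(stack, bin) {
  v <- stack$voxels
  d <- dim(v)
  A <- 0
  for (y in seq_len(d[2]))
    A <- A + Mod(stats::fft(matrix(as.numeric(v[, y, ]), nrow = d[1])))
  A <- A / d[2]
  band <- median(A[(bin - 8):(bin + 8), 1][-9])
  (A[bin, 1] / band)^2
}

# Mean absolute finite difference of en-face slices along one axis:
# the independent directional-energy oracle for the wavelet features.
fd_energy <- function(stack, axis = c("x", "y")) {
  axis <- match.arg(axis)
  v <- stack$voxels
  if (axis == "x") {
    mean(abs(v[, , -1, drop = FALSE] - v[, , -dim(v)[3], drop = FALSE]))
  } else {
    mean(abs(v[, -1, , drop = FALSE] - v[, -dim(v)[2], , drop = FALSE]))
  }
}
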