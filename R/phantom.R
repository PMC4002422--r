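#' Specify a synthetic OCT speckle phantom
#'
#' The phantom emulates a coherently imaged cell layer on a coverslip:
#' fully developed speckle whose spatial correlation structure drifts with a
#' `degeneration` parameter, plus the nuisance structure the preprocessing
#' pipeline removes (a bright tilted coverslip plane, fixed-pattern line
#' artifacts, background noise).
#'
#' Degeneration maps to the scatterer field the way early apoptosis
#' reorganizes organelles: at `degeneration = 0` the medium is made of
#' relatively large scatterer clumps (filamentous-network-like texture); as
#' `degeneration` grows each clump fragments in place into a smaller,
#' rounder body (radius shrinking linearly to 40% at `degeneration = 1`,
#' clump count constant), which shrinks the intensity envelope's
#' correlation length and the binary particle sizes monotonically across
#' the whole range.
#'
#' @param shape voxel dimensions `(z, y, x)`, each at least 16.
#' @param voxel_pitch_um transverse voxel pitch (um). The default 1.46 um
#'   corresponds to 1024 px spanning 1492 um.
#' @param scatterer_density expected scatterer seeds per voxel at
#'   `degeneration = 0`.
#' @param scatterer_radius_vox scatterer clump radius in voxels at
#'   `degeneration = 0`.
#' @param degeneration real in `[0, 1]`; 0 = control texture, 1 = maximal
#'   fragmentation.
#' @param psf_sigma_vox Gaussian point-spread-function sigma `(z, y, x)` in
#'   voxels (axial / lateral blur).
#' @param tilt_deg coverslip tilt in degrees about the three cardinal
#'   directions. The first two entries tilt the plane along y and x; the
#'   third (rotation about the optical axis) leaves a plane invariant and is
#'   accepted but has no effect.
#' @param line_artifact_amp amplitude (quantization levels) of the
#'   fixed-pattern sinusoidal line artifact along depth.
#' @param line_artifact_freq artifact frequency in cycles/voxel along z.
#' @param background_sigma sd (quantization levels) of additive Gaussian
#'   background noise.
#' @param bit_depth quantization bit depth.
#' @param seed integer seed; identical specs with identical seeds produce
#'   bit-identical stacks.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(128L, 64L, 64L),
                         voxel_pitch_um = 1.46,
                         scatterer_density = 0.02,
                         scatterer_radius_vox = 3.5,
                         degeneration = 0,
                         psf_sigma_vox = c(1.4, 1.1, 1.1),
                         tilt_deg = c(0, 0, 0),
                         line_artifact_amp = 12,
                         line_artifact_freq = 0.28125,
                         background_sigma = 2,
                         bit_depth = 8L,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), voxel_pitch_um = voxel_pitch_um,
               scatterer_density = scatterer_density,
               scatterer_radius_vox = scatterer_radius_vox,
               degeneration = degeneration, psf_sigma_vox = psf_sigma_vox,
               tilt_deg = tilt_deg, line_artifact_amp = line_artifact_amp,
               line_artifact_freq = line_artifact_freq,
               background_sigma = background_sigma,
               bit_depth = as.integer(bit_depth), seed = as.integer(seed))
  validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid phantom spec: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (length(spec$shape) != 3L || any(spec$shape < 16L))
    fail("shape", "must be a (z,y,x) triple with all components >= 16")
  if (spec$voxel_pitch_um <= 0) fail("voxel_pitch_um", "must be positive")
  if (spec$scatterer_density < 0) fail("scatterer_density", "must be >= 0")
  if (spec$scatterer_radius_vox <= 0)
    fail("scatterer_radius_vox", "must be positive")
  if (spec$degeneration < 0 || spec$degeneration > 1)
    fail("degeneration", "must lie in [0, 1]")
  if (length(spec$psf_sigma_vox) != 3L || any(spec$psf_sigma_vox <= 0))
    fail("psf_sigma_vox", "must be a positive triple")
  if (length(spec$tilt_deg) != 3L || any(!is.finite(spec$tilt_deg)))
    fail("tilt_deg", "must be a finite triple")
  if (spec$line_artifact_amp < 0) fail("line_artifact_amp", "must be >= 0")
  if (spec$line_artifact_freq <= 0 || spec$line_artifact_freq >= 0.5)
    fail("line_artifact_freq", "must lie in (0, 0.5) cycles/voxel")
  if (spec$background_sigma < 0) fail("background_sigma", "must be >= 0")
  if (spec$bit_depth < 1L) fail("bit_depth", "must be a positive integer")
  invisible(spec)
}

# Circular (wrap-around) FFT convolution of a real 3D array with a kernel
# given in the frequency domain.
conv3_fft <- function(a, kernel_fft) {
  Re(fft(fft(a) * kernel_fft, inverse = TRUE)) / length(a)
}

# Frequency response of a kernel defined by wrapped distance from the origin.
wrapped_kernel_fft <- function(d, fun) {
  ax <- lapply(d, function(n) {
    i <- 0:(n - 1)
    pmin(i, n - i)
  })
  dz <- array(ax[[1]], dim = d)
  dy <- aperm(array(ax[[2]], dim = d[c(2, 1, 3)]), c(2, 1, 3))
  dx <- aperm(array(ax[[3]], dim = d[c(3, 2, 1)]), c(3, 2, 1))
  fft(fun(dz, dy, dx))
}

#' Generate a synthetic OCT speckle stack
#'
#' The simulation chain: (a) a Poisson seed field below the coverslip is
#' convolved with a spherical clump kernel whose radius shrinks with
#' `degeneration`, giving a scatterer strength map;
#' (b) a circular complex Gaussian phasor field weighted by the square root
#' of that map is blurred with the Gaussian PSF and magnitude-detected,
#' yielding fully developed speckle with a degeneration-dependent envelope;
#' (c) a bright coverslip plane tilted per `tilt_deg` is added; (d) a
#' fixed-pattern sinusoidal line artifact along depth and (e) Gaussian
#' background noise are added; (f) the result is quantized to `bit_depth`.
#'
#' The returned stack carries a `truth` attribute with the injected
#' coverslip plane, tilt and the active (speckle-bearing) z-range, for use
#' as ground truth when validating the preprocessing stages.
#'
#' @param spec a [phantom_spec()].
#' @return An [image_stack()].
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  maxlev <- 2^spec$bit_depth - 1

  z_cs <- max(4, round(0.12 * nz))
  z_lo <- z_cs + 5
  # the cell layer occupies a slab below the coverslip; deeper voxels are
  # medium (background noise only), which gives ROI masking a boundary
  z_hi <- min(nz, z_lo + max(8, round(0.7 * (nz - z_lo))))
  active <- seq(z_lo, z_hi)

  deg <- spec$degeneration
  r_eff <- spec$scatterer_radius_vox * (1 - 0.6 * deg)
  lam_eff <- spec$scatterer_density

  env <- array(0, dim = d)
  if (lam_eff > 0) {
    seeds <- array(0, dim = d)
    seeds[active, , ] <- rpois(length(active) * ny * nx, lam_eff)
    ball_fft <- wrapped_kernel_fft(d, function(dz, dy, dx) {
      (dz^2 + dy^2 + dx^2 <= r_eff^2) * 1
    })
    rho <- conv3_fft(seeds, ball_fft)
    rho[rho < 0] <- 0
    mu <- mean(rho[active, , ])
    if (mu > 0) rho <- rho / mu

    g_re <- array(rnorm(prod(d)), dim = d) * sqrt(rho)
    g_im <- array(rnorm(prod(d)), dim = d) * sqrt(rho)
    s <- spec$psf_sigma_vox
    psf_fft <- wrapped_kernel_fft(d, function(dz, dy, dx) {
      exp(-0.5 * ((dz / s[1])^2 + (dy / s[2])^2 + (dx / s[3])^2))
    })
    fld <- complex(real = g_re, imaginary = g_im)
    dim(fld) <- d
    env <- Mod(fft(fft(fld) * psf_fft, inverse = TRUE)) / prod(d)
    # soft (raised-cosine, ~3 voxel) axial edges of the cell slab: real
    # layers do not end in step functions, and razor edges would put
    # strong oscillatory structure on the fixed-pattern spectral lines
    ramp <- 3
    wz <- pmin(1, pmax(0, (seq_len(nz) - (z_lo - ramp)) / ramp)) *
      pmin(1, pmax(0, ((z_hi + ramp) - seq_len(nz)) / ramp))
    wz <- sin(wz * pi / 2)^2
    env <- env * wz
    m_env <- mean(env[active, , ])
    if (m_env > 0) env <- env * (0.35 * maxlev / m_env)
  }

  # diagnostic: a subsample of the pre-quantization speckle amplitudes from
  # the slab interior (clear of the edge ramps), for realism checks
  speckle_sample <- NULL
  if (lam_eff > 0 && length(active) > 8) {
    core <- env[(z_lo + 3):(z_hi - 3), , ]
    idx <- round(seq(1, length(core), length.out = min(10000, length(core))))
    speckle_sample <- as.numeric(core[idx])
  }

  # coverslip plane with tilt
  t1 <- tan(spec$tilt_deg[1] * pi / 180)
  t2 <- tan(spec$tilt_deg[2] * pi / 180)
  yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
  plane_z <- outer(seq_len(ny) - yc, seq_len(nx) - xc,
                   function(yy, xx) z_cs + t1 * yy + t2 * xx)
  zs <- seq_len(nz)
  cs_sigma <- 1.2
  cs <- vapply(seq_len(nx), function(x) {
    outer(zs, plane_z[, x], function(z, z0) exp(-(z - z0)^2 / (2 * cs_sigma^2)))
  }, matrix(0, nz, ny))
  env <- env + 0.92 * maxlev * cs

  # fixed-pattern line artifact along depth, identical in every A-scan
  if (spec$line_artifact_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    la <- spec$line_artifact_amp *
      sin(2 * pi * spec$line_artifact_freq * zs + phase)
    env <- env + array(la, dim = d)
  }

  if (spec$background_sigma > 0)
    env <- env + array(rnorm(prod(d), sd = spec$background_sigma), dim = d)

  stk <- image_stack(env, spec$voxel_pitch_um, spec$bit_depth,
                     metadata = list(degeneration = format(deg),
                                     seed = format(spec$seed)))
  attr(stk, "truth") <- list(coverslip_z = z_cs, plane_z = plane_z,
                             tilt_deg = spec$tilt_deg,
                             active_z = c(z_lo, z_hi),
                             speckle_sample = speckle_sample)
  stk
}

#' Generate a degeneration time course of phantom stacks
#'
#' Produces `n_per_point` stacks per schedule entry. Per-stack seeds are
#' drawn from a stream seeded by `base$seed`, so the whole time course is
#' reproducible from the base spec alone. Stack metadata records the
#' timepoint index (1-based), the schedule value and a replicate id.
#'
#' @param base a [phantom_spec()] used as the template.
#' @param degeneration_schedule numeric vector of degeneration values in
#'   `[0, 1]`, one per timepoint.
#' @param n_per_point stacks per timepoint (>= 1).
#' @return A list of [image_stack()] objects, ordered timepoint-major.
#' @export
generate_timecourse <- function(base, degeneration_schedule, n_per_point) {
  if (length(degeneration_schedule) == 0)
    stop("degeneration_schedule must be nonempty")
  if (any(degeneration_schedule < 0 | degeneration_schedule > 1))
    stop("degeneration_schedule values must lie in [0, 1]")
  n_per_point <- as.integer(n_per_point)
  if (n_per_point < 1L) stop("n_per_point must be >= 1")

  nT <- length(degeneration_schedule)
  set.seed(base$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, nT * n_per_point),
                  nrow = nT)
  out <- vector("list", nT * n_per_point)
  idx <- 0L
  for (t in seq_len(nT)) {
    for (i in seq_len(n_per_point)) {
      sp <- base
      sp$degeneration <- degeneration_schedule[t]
      sp$seed <- seeds[t, i]
      class(sp) <- "phantom_spec"
      stk <- generate_phantom(sp)
      stk$metadata$timepoint <- format(t)
      stk$metadata$schedule_value <- format(degeneration_schedule[t])
      stk$metadata$replicate <- format(i)
      idx <- idx + 1L
      out[[idx]] <- stk
    }
  }
  out
}
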