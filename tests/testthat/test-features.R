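test_that("the registry holds 65 features in the canonical groups", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 65L)
  expect_identical(as.integer(table(factor(reg$group,
    levels = c("local_stats", "moments", "cooccurrence", "granulometry",
               "wavelet")))), c(12L, 2L, 12L, 21L, 18L))
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("a constant stack yields the documented degenerate vector", {
  v <- array(120L, dim = c(24, 24, 24))
  stk <- image_stack(v)
  roi <- full_roi(stk)
  ls <- local_stat_features(stk, roi)
  expect_true(all(ls == 0))
  expect_warning(mm <- moment_features(stk, roi), "zero")
  expect_identical(unname(mm), c(0, 0))
  cc <- cooccurrence_features(stk, roi)
  expect_equal(unname(cc[c("cooc_x_contrast", "cooc_y_contrast",
                           "cooc_z_contrast")]), c(0, 0, 0))
  expect_equal(unname(cc[grep("energy|homogeneity|correlation", names(cc))]),
               rep(1, 9))
  gr <- granulometry_features(stk, roi)
  expect_true(all(gr == 0))   # all-white ROI: nothing below threshold
  wv <- wavelet_features(stk, roi)
  expect_true(all(wv == 0))
})

test_that("checkerboard local range saturates at the full gray range", {
  idx <- expand.grid(z = 1:20, y = 1:20, x = 1:20)
  v <- array(255L * ((idx$z + idx$y + idx$x) %% 2L), dim = c(20, 20, 20))
  stk <- image_stack(v)
  ls <- local_stat_features(stk, full_roi(stk))
  expect_equal(unname(ls["ls_range_mean"]), 1)
  expect_equal(unname(ls["ls_range_sd"]), 0)
  expect_equal(unname(ls["ls_range_entropy"]), 0)
})

test_that("moments match closed forms and large-sample normality", {
  v <- array(0L, dim = c(20, 20, 20))
  v[, , 1:10] <- 255L      # equal-mass two-point distribution
  stk <- image_stack(v)
  mm <- moment_features(stk, full_roi(stk))
  expect_equal(unname(mm["mom_skewness"]), 0, tolerance = 1e-12)
  expect_equal(unname(mm["mom_kurtosis"]), 1, tolerance = 1e-12)

  set.seed(8)
  g <- array(round(pmin(pmax(rnorm(50^3, 128, 20), 0), 255)),
             dim = c(50, 50, 50))
  gm <- moment_features(image_stack(g), full_roi(image_stack(g)))
  expect_lt(abs(gm["mom_skewness"]), 0.05)
  expect_lt(abs(gm["mom_kurtosis"] - 3), 0.1)
})

test_that("co-occurrence statistics match the periodic-stripe oracle", {
  # stripes of period 10 along x: 5 dark then 5 bright columns
  v <- array(0L, dim = c(16, 16, 40))
  bright <- ((0:39) %% 10) >= 5
  v[, , bright] <- 255L
  stk <- image_stack(v)
  cc <- cooccurrence_features(stk, full_roi(stk), offset_vox = 5)
  expect_equal(unname(cc["cooc_x_contrast"]), 49)   # (levels-1)^2
  expect_equal(unname(cc["cooc_z_contrast"]), 0)
  expect_equal(unname(cc["cooc_y_contrast"]), 0)

  set.seed(3)
  u <- array(sample(0:255, 48^3, replace = TRUE), dim = c(48, 48, 48))
  cu <- cooccurrence_features(image_stack(u), full_roi(image_stack(u)))
  expect_equal(unname(cu["cooc_x_energy"]), 1 / 64, tolerance = 0.02)
  expect_lt(abs(cu["cooc_x_correlation"]), 0.02)
})

test_that("co-occurrence errors name an axis without valid pairs", {
  stk <- cube_stack(dim3 = c(24, 24, 24), lo = 10, hi = 13)
  roi <- roi_from_mask(array(stk$voxels > 0, dim = dim(stk$voxels)))
  expect_error(cooccurrence_features(stk, roi, offset_vox = 5), "axis")
})

test_that("granulometry histograms localize hand-placed particles", {
  v <- array(255L, dim = c(24, 24, 24))
  v[10:11, 10:11, 10:11] <- 0L   # one black particle of 8 voxels -> bin 4
  stk <- image_stack(v)
  gr <- granulometry_features(stk, full_roi(stk))
  want12 <- numeric(12); want12[4] <- 1
  expect_equal(unname(gr[1:12]), want12)
  want6 <- numeric(6); want6[2] <- 1
  expect_equal(unname(gr[13:18]), want6)
  want3 <- numeric(3); want3[1] <- 1
  expect_equal(unname(gr[19:21]), want3)

  v2 <- array(255L, dim = c(24, 24, 24))
  v2[4, 4, 4] <- 0L                 # size 1 -> bin 1
  v2[12, 12, 12:13] <- 0L           # size 2 -> bin 2
  gr2 <- granulometry_features(image_stack(v2), full_roi(image_stack(v2)))
  expect_equal(unname(gr2[1:3]), c(0.5, 0.5, 0))
  expect_equal(unname(gr2[13:14]), c(1, 0))
})

test_that("directional wavelet features see stripe orientation", {
  v <- array(0L, dim = c(12, 48, 48))
  v[, , ((0:47) %% 8) < 4] <- 200L   # variation along x only
  stk <- image_stack(v)
  roi <- full_roi(stk)
  wv <- wavelet_features(stk, roi)
  for (s in 1:3) {
    expect_gt(wv[sprintf("wav_x_s%d_mean", s)],
              wv[sprintf("wav_y_s%d_mean", s)])
  }
  # independent oracle: finite-difference energy is also x-dominated
  expect_gt(fd_energy(stk, "x"), fd_energy(stk, "y"))
})

test_that("a 90-degree in-plane rotation swaps x and y wavelet features", {
  stk <- preprocess_stack(quick_phantom(seed = 81, shape = c(32, 40, 40)),
                          crop_below_coverslip = TRUE)$stack
  roi <- mask_roi_auto(stk)
  rot_v <- aperm(stk$voxels, c(1, 3, 2))[, , dim(stk$voxels)[2]:1]
  rot_m <- aperm(roi$mask, c(1, 3, 2))[, , dim(roi$mask)[2]:1]
  w1 <- wavelet_features(stk, roi)
  w2 <- wavelet_features(with_voxels(stk, rot_v), roi_from_mask(rot_m))
  for (s in 1:3) for (st in c("mean", "sd")) {
    a <- w1[sprintf("wav_x_s%d_%s", s, st)]
    b <- w2[sprintf("wav_y_s%d_%s", s, st)]
    expect_lt(abs(a - b) / a, 0.05)
    d1 <- w1[sprintf("wav_diag_s%d_%s", s, st)]
    d2 <- w2[sprintf("wav_diag_s%d_%s", s, st)]
    expect_lt(abs(d1 - d2) / d1, 0.05)
  }
})

test_that("extract_features returns 65 finite values, deterministically", {
  stk <- preprocess_stack(quick_phantom(seed = 82),
                          crop_below_coverslip = TRUE)$stack
  roi <- mask_roi_auto(stk)
  eq <- equalize_in_roi(stk, roi)
  f1 <- extract_features(eq, roi)
  expect_length(f1, 65)
  expect_true(all(is.finite(f1)))
  expect_identical(names(f1), feature_registry()$name)
  f2 <- extract_features(eq, roi)
  expect_identical(as.numeric(f1), as.numeric(f2))
})

test_that("features are invariant to whole-voxel translation", {
  set.seed(12)
  block <- array(sample(0:255, 20^3, replace = TRUE), dim = c(20, 20, 20))
  place <- function(off) {
    v <- array(0L, dim = c(44, 44, 44))
    v[off[1] + 1:20, off[2] + 1:20, off[3] + 1:20] <- block
    m <- array(FALSE, dim = c(44, 44, 44))
    m[off[1] + 1:20, off[2] + 1:20, off[3] + 1:20] <- TRUE
    extract_features(image_stack(v), roi_from_mask(m))
  }
  fa <- place(c(10, 10, 10))
  fb <- place(c(13, 11, 12))
  expect_lt(max(abs(fa - fb)), 1e-9)
})

test_that("component labeling agrees with the BFS oracle", {
  set.seed(5)
  for (conn in c(6L, 26L)) {
    m <- array(runif(14^3) < 0.35, dim = c(14, 14, 14))
    a <- array(speckletex:::cpp_label3d(as.logical(m), dim(m), conn),
               dim = dim(m))
    b <- bfs_label3d(m, conn)
    expect_identical(max(a), max(b))
    # same partition: labels must be a bijection
    expect_identical(length(unique(paste(a[m], b[m]))), max(a))
  }
})

test_that("ROIs smaller than the neighborhood or scales are rejected", {
  stk <- cube_stack(dim3 = c(24, 24, 24), lo = 11, hi = 13)
  roi <- roi_from_mask(array(stk$voxels > 0, dim = dim(stk$voxels)))
  expect_error(local_stat_features(stk, roi), "neighborhood")
  expect_error(wavelet_features(stk, roi), "too small")
})

test_that("the feature registry serializes to a JSON reference", {
  path <- file.path(tempdir(), "registry.json")
  write_feature_registry(path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(back), 65L)
  expect_identical(back$name, feature_registry()$name)
  unlink(path)
})

test_that("many features separate control from degenerated texture", {
  batch <- function(deg, seed0) {
    base <- phantom_spec(shape = c(48, 40, 40), degeneration = deg,
                         seed = seed0)
    stks <- generate_timecourse(base, deg, 20)
    do.call(rbind, lapply(stks, function(s) stack_to_features(s)$features))
  }
  F0 <- batch(0, 9001)
  F1 <- batch(1, 9002)
  d <- vapply(seq_len(65), function(j) {
    sp <- sqrt((var(F0[, j]) + var(F1[, j])) / 2)
    if (sp == 0) 0 else (mean(F1[, j]) - mean(F0[, j])) / sp
  }, numeric(1))
  expect_gte(sum(abs(d) > 1), 10)
})
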