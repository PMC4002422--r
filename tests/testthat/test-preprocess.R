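test_that("coverslip detection recovers injected tilt", {
  flat <- quick_phantom(seed = 21, shape = c(64, 64, 64))
  pl <- detect_coverslip(flat)
  expect_lt(abs(pl$tilt_y_deg), 0.5)
  expect_lt(abs(pl$tilt_x_deg), 0.5)
  ang <- acos(pl$normal[1]) * 180 / pi
  expect_lt(ang, 0.5)    # plane normal within 0.5 degrees of the axial axis

  tilted <- generate_phantom(phantom_spec(shape = c(64, 64, 64),
                                          tilt_deg = c(2, 1, 0), seed = 22))
  pl2 <- detect_coverslip(tilted)
  expect_lt(abs(pl2$tilt_y_deg - 2), 0.5)
  expect_lt(abs(pl2$tilt_x_deg - 1), 0.5)
})

test_that("an empty stack has no coverslip", {
  z <- image_stack(array(0, dim = c(32, 32, 32)))
  expect_error(detect_coverslip(z), "no coverslip")
})

test_that("tilt removal flattens the coverslip and refuses extreme tilt", {
  tilted <- generate_phantom(phantom_spec(shape = c(64, 64, 64),
                                          tilt_deg = c(3, -2, 0), seed = 31))
  pl <- detect_coverslip(tilted)
  fixed <- remove_tilt(tilted, pl)
  expect_identical(dim(fixed$voxels), dim(tilted$voxels))
  pl2 <- detect_coverslip(fixed)
  # post-correction coverslip depth varies by <= 1 voxel across the field
  d <- dim(fixed$voxels)
  span <- abs(pl2$slope_y) * d[2] + abs(pl2$slope_x) * d[3]
  expect_lt(span, 1)

  expect_error(remove_tilt(tilted, list(b0 = 10, slope_y = tan(40 * pi / 180),
                                        slope_x = 0)), "limit")
})

test_that("zero-tilt plane removal is the identity", {
  stk <- quick_phantom(seed = 33)
  out <- remove_tilt(stk, list(b0 = 10, slope_y = 0, slope_x = 0))
  expect_identical(out$voxels, stk$voxels)
})

test_that("shear and inverse shear nearly round-trip", {
  stk <- quick_phantom(seed = 34, shape = c(64, 48, 48))
  pl <- list(b0 = 10, slope_y = 0.03, slope_x = -0.02)
  inv <- list(b0 = 10, slope_y = -0.03, slope_x = 0.02)
  back <- remove_tilt(remove_tilt(stk, pl), inv)
  d <- dim(stk$voxels)
  keep <- 4:(d[1] - 4)   # clear of the shifted-out border
  expect_gt(cor(as.numeric(back$voxels[keep, , ]),
                as.numeric(stk$voxels[keep, , ])), 0.98)
})

test_that("notch filter removes the fixed-pattern artifact, not the image", {
  stk <- quick_phantom(seed = 41, shape = c(64, 48, 48))
  filt <- remove_line_artifacts(stk)
  expect_gte(attr(filt, "n_notched"), 2)
  bin <- round(phantom_spec()$line_artifact_freq * 64) + 1
  expect_gt(avg_peak_ratio(stk, bin), 2)    # visible before filtering
  expect_lt(avg_peak_ratio(filt, bin), 2)   # suppressed below 2x band

  clean <- quick_phantom(seed = 42, line_artifact_amp = 0)
  out <- remove_line_artifacts(clean)
  expect_lt(sqrt(mean((out$voxels - clean$voxels)^2)), 1)
})

test_that("a pure sinusoidal fixed pattern is annihilated", {
  v <- array(0, dim = c(64, 32, 64))
  v[] <- 100 + 50 * sin(2 * pi * 0.28125 * (1:64))
  stk <- image_stack(v)
  out <- remove_line_artifacts(stk)
  bin <- round(0.28125 * 64) + 1
  P0 <- Mod(fft(matrix(as.numeric(stk$voxels[, 1, ]), 64)))[bin, 1]^2
  P1 <- Mod(fft(matrix(as.numeric(out$voxels[, 1, ]), 64)))[bin, 1]^2
  expect_lt(P1, 0.01 * P0)
})

test_that("reflection streaks are clipped to the local median", {
  stk <- quick_phantom(seed = 51, shape = c(48, 32, 32))
  v <- stk$voxels
  v[20:30, 16, 16] <- 255L   # an 11-voxel saturated streak
  sat <- with_voxels(stk, v)
  out <- remove_reflections(sat)
  expect_true(all(out$voxels[22:28, 16, 16] < 255))
  # voxels outside the streak untouched
  v2 <- out$voxels; v2[19:31, 15:17, 15:17] <- sat$voxels[19:31, 15:17, 15:17]
  expect_identical(v2, sat$voxels)
})

test_that("the full pipeline preserves geometry and is nearly idempotent", {
  stk <- generate_phantom(phantom_spec(shape = c(64, 48, 48),
                                       tilt_deg = c(1.5, -1, 0), seed = 61))
  p1 <- preprocess_stack(stk)
  expect_identical(dim(p1$stack$voxels), dim(stk$voxels))
  expect_identical(p1$stack$bit_depth, stk$bit_depth)
  expect_length(p1$report$applied_tilts_deg, 3)
  p2 <- preprocess_stack(p1$stack)
  expect_lt(sqrt(mean((p2$stack$voxels - p1$stack$voxels)^2)), 1)

  cropped <- preprocess_stack(stk, crop_below_coverslip = TRUE)
  cb <- cropped$report$crop_box
  expect_identical(dim(cropped$stack$voxels)[1],
                   unname(cb["z", 2] - cb["z", 1]))
})

test_that("preprocess reports serialize to JSON", {
  pp <- preprocess_stack(quick_phantom(seed = 62), crop_below_coverslip = TRUE)
  path <- file.path(tempdir(), "report.json")
  write_preprocess_report(pp$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coverslip_plane$b0, pp$report$coverslip_plane$b0)
  expect_identical(back$n_artifact_frequencies_notched,
                   pp$report$n_artifact_frequencies_notched)
  expect_identical(as.integer(back$crop_box$z),
                   as.integer(pp$report$crop_box["z", ]))
  unlink(path)
})
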