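test_that("lateral profiles: uniform, half-field, and brute-force oracle", {
  dims <- c(8, 10, 6); spacing <- c(1, 0.5, 0.5)
  st <- image_stack(array(7, dims), array(3, dims), spacing)
  pr <- lateral_profile(st, "x", c(0, 6))
  expect_equal(pr$red_intensity, rep(7, 10))
  expect_equal(pr$green_intensity, rep(3, 10))
  expect_equal(pr$position_um, (1:10 - 0.5) * 0.5)

  green <- array(0, dims); green[, 1:5, ] <- 50
  st <- image_stack(array(0, dims), green, spacing)
  pr <- lateral_profile(st, "x", c(0, 6))
  expect_equal(pr$green_intensity, c(rep(50, 5), rep(0, 5)))
  expect_true(all(pr$red_intensity == 0))

  st <- random_stack(dims, spacing)
  z_range <- c(1, 4)
  pr <- lateral_profile(st, "y", z_range)
  zc <- (seq_len(dims[3]) - 0.5) * spacing[1]
  slices <- which(zc >= z_range[1] & zc < z_range[2])
  for (iy in seq_len(dims[1])) {   # exhaustive averaging oracle
    expect_equal(pr$red_intensity[iy], mean(st$red[iy, , slices]))
    expect_equal(pr$green_intensity[iy], mean(st$green[iy, , slices]))
  }

  expect_error(lateral_profile(st, "x", c(5, 5)), "lo < hi")
  expect_error(lateral_profile(st, "x", c(100, 110)), "empty z range")
})

test_that("profiles are invariant to permuting planes orthogonal to the axis", {
  st <- random_stack(c(8, 10, 6), c(1, 0.5, 0.5))
  perm <- sample(8)
  st2 <- image_stack(st$red[perm, , ], st$green[perm, , ], st$voxel_spacing)
  expect_equal(lateral_profile(st, "x", c(0, 6)),
               lateral_profile(st2, "x", c(0, 6)))
})

test_that("whole-image intensity is the per-channel mean", {
  dims <- c(4, 4, 4)
  expect_equal(
    whole_image_intensity(image_stack(array(0, dims), array(0, dims), c(1, 1, 1))),
    c(red_mean = 0, green_mean = 0))
  expect_equal(
    whole_image_intensity(image_stack(array(10, dims), array(20, dims), c(1, 1, 1))),
    c(red_mean = 10, green_mean = 20))
  # checkerboard 0/8 -> mean 4
  cb <- array(0, dims)
  cb[(slice.index(cb, 1) + slice.index(cb, 2) + slice.index(cb, 3)) %% 2 == 0] <- 8
  expect_equal(unname(whole_image_intensity(image_stack(cb, cb, c(1, 1, 1)))[1]), 4)
})

test_that("co-localization fraction uses exact physical distances", {
  dims <- c(12, 12, 8); spacing <- c(2, 1, 1)  # (dz, dy, dx)
  red <- array(FALSE, dims); red[6, 6, 4] <- TRUE
  green <- array(FALSE, dims)
  green[6, 9, 4] <- TRUE   # 3 voxels along x = 3 um
  expect_equal(coloc_fraction(green, red, radius = 3, spacing)$green_coloc_fraction, 1)
  expect_equal(coloc_fraction(green, red, radius = 2.9, spacing)$green_coloc_fraction, 0)

  green2 <- array(FALSE, dims)
  green2[6, 6, 6] <- TRUE  # 2 slices along z = 4 um
  expect_equal(coloc_fraction(green2, red, radius = 4, spacing)$green_coloc_fraction, 1)
  expect_equal(coloc_fraction(green2, red, radius = 3.9, spacing)$green_coloc_fraction, 0)

  # green entirely inside the dilated red neighborhood
  red2 <- array(FALSE, dims); red2[5:8, 5:8, 3:5] <- TRUE
  green3 <- array(FALSE, dims); green3[6:7, 6:7, 4] <- TRUE
  expect_equal(coloc_fraction(green3, red2, radius = 1, spacing)$green_coloc_fraction, 1)

  # empty masks
  none <- array(FALSE, dims)
  res <- coloc_fraction(none, red, radius = 5, spacing)
  expect_equal(res$green_coloc_fraction, 0)
  expect_true(res$green_empty)
  expect_equal(coloc_fraction(green, none, radius = 5, spacing)$green_coloc_fraction, 0)

  expect_error(coloc_fraction(green, array(FALSE, c(2, 2, 2)), 5, spacing), "shape")
})

test_that("co-localization fraction is non-decreasing in the radius", {
  set.seed(3)
  dims <- c(14, 14, 10); spacing <- c(1.5, 0.8, 0.8)
  red <- array(runif(prod(dims)) > 0.95, dims)
  green <- array(runif(prod(dims)) > 0.9, dims)
  radii <- c(0.5, 1, 2, 4, 8, 16)
  fr <- vapply(radii, function(r) {
    coloc_fraction(green, red, r, spacing)$green_coloc_fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("retention analysis classifies and scores wash-out correctly", {
  dims <- c(12, 12, 8); spacing <- c(1, 1, 1)
  red <- array(FALSE, dims); red[5:7, 5:7, 3:5] <- TRUE
  green <- array(FALSE, dims)
  green[8, 8, 4] <- TRUE     # adjacent to red (coloc at radius 2)
  green[1, 1, 1] <- TRUE     # far corner (non-coloc)
  before <- list(red = red, green = green)

  same <- retention_analysis(before, list(green = green), radius = 2, spacing = spacing)
  expect_equal(same$retained_coloc_fraction, 1)
  expect_equal(same$retained_noncoloc_fraction, 1)

  gone <- retention_analysis(before, list(green = array(FALSE, dims)),
                             radius = 2, spacing = spacing)
  expect_equal(gone$retained_coloc_fraction, 0)
  expect_equal(gone$retained_noncoloc_fraction, 0)

  # selective wash-out removes only the non-co-localized cell
  washed <- green; washed[1, 1, 1] <- FALSE
  sel <- retention_analysis(before, list(green = washed), radius = 2, spacing = spacing)
  expect_equal(sel$retained_coloc_fraction, 1)
  expect_equal(sel$retained_noncoloc_fraction, 0)

  expect_error(
    retention_analysis(before, list(green = array(FALSE, c(2, 2, 2))),
                       radius = 2, spacing = spacing),
    "misaligned")
})
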