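make_uniform_stack <- function(red_val, green_val, dims = c(8, 8, 32),
                               spacing = c(1, 0.5, 0.5)) {
  image_stack(array(red_val, dims), array(green_val, dims), spacing)
}

test_that("red segmentation: empty and saturated channels behave as expected", {
  p <- segmentation_params(smoothing_sigma = 0, min_object_voxels = 1)
  st <- make_uniform_stack(0, 0)
  expect_false(any(segment_red(st, p)$mask))
  st <- make_uniform_stack(255, 0)
  expect_true(all(segment_red(st, p)$mask))
})

test_that("noise-free phantom red mask equals the brute-force threshold set", {
  p <- degradation_off(small_phantom_params(seed = 21L))
  res <- generate_phantom(p)
  sp <- segmentation_params(red_threshold = 30, smoothing_sigma = 0,
                            min_object_voxels = 1)
  mask <- segment_red(res$stack, sp)$mask
  expect_identical(mask, res$stack$red > 30)
})

test_that("masking the green channel by the red mask is exact and non-destructive", {
  dims <- c(10, 10, 8)
  green <- array(runif(prod(dims), 0, 255), dims)
  green_copy <- green

  empty <- array(FALSE, dims)
  expect_identical(mask_green_by_red(green, empty), green)

  full <- array(TRUE, dims)
  expect_true(all(mask_green_by_red(green, full) == 0))

  m <- array(runif(prod(dims)) > 0.5, dims)
  out <- mask_green_by_red(green, m)
  # elementwise oracle
  for (i in sample(length(green), 200)) {
    expect_identical(out[i], if (m[i]) 0 else green[i])
  }
  expect_identical(green, green_copy)  # input untouched

  expect_error(mask_green_by_red(green, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("green segmentation applies per-depth thresholds by voxel-center membership", {
  p <- segmentation_params(smoothing_sigma = 0, min_object_voxels = 1)
  empty_red <- array(FALSE, c(8, 8, 32))
  segs <- default_depth_segments()

  st <- make_uniform_stack(0, 0)
  expect_false(any(segment_green(st, empty_red, p, segs)$mask))

  # green 20 beats every threshold (14/12/10) inside configured segments
  st <- make_uniform_stack(0, 20)
  g <- segment_green(st, empty_red, p, segs)
  zc <- (seq_len(32) - 0.5) * 1
  configured <- zc < 30
  expect_true(all(g$mask[, , configured]))
  expect_false(any(g$mask[, , !configured]))
  expect_equal(g$unsegmented_voxels, sum(!configured) * 8 * 8)

  # green 11 only beats the deepest segment's threshold (10 on 20-30 um)
  st <- make_uniform_stack(0, 11)
  g <- segment_green(st, empty_red, p, segs)
  in_deep <- zc >= 20 & zc < 30
  expect_true(all(g$mask[, , in_deep]))
  expect_false(any(g$mask[, , !in_deep]))

  # masking precedes thresholding: saturated green under a full red mask
  st <- make_uniform_stack(0, 255)
  full_red <- array(TRUE, c(8, 8, 32))
  expect_false(any(segment_green(st, full_red, p, segs)$mask))
})

test_that("green and red masks are mutually exclusive on random stacks", {
  for (i in 1:20) {
    st <- random_stack(dims = c(12, 12, 16), spacing = c(2, 1, 1))
    sp <- segmentation_params(
      red_threshold = runif(1, 5, 60),
      green_thresholds = runif(2, 5, 40),
      smoothing_sigma = sample(c(0, 0.5, 1), 1),
      min_object_voxels = sample(1:8, 1)
    )
    segs <- depth_segments(c(0, 16, 32))
    red <- segment_red(st, sp)
    green <- segment_green(st, red, sp, segs)
    expect_equal(sum(green$mask & red$mask), 0L)
  }
})

test_that("raising a threshold never adds voxels to a mask", {
  st <- random_stack(dims = c(12, 12, 16), spacing = c(2, 1, 1))
  segs <- depth_segments(c(0, 16, 32))
  lo <- segmentation_params(red_threshold = 20, green_thresholds = c(10, 10),
                            smoothing_sigma = 0.5, min_object_voxels = 1)
  hi <- segmentation_params(red_threshold = 35, green_thresholds = c(22, 22),
                            smoothing_sigma = 0.5, min_object_voxels = 1)
  red_lo <- segment_red(st, lo); red_hi <- segment_red(st, hi)
  expect_true(all(red_lo$mask | !red_hi$mask))   # hi subset of lo
  g_lo <- segment_green(st, red_lo, lo, segs)
  g_hi <- segment_green(st, red_lo, hi, segs)
  expect_true(all(g_lo$mask | !g_hi$mask))
})

test_that("small-object removal drops components below the cutoff only", {
  m <- array(FALSE, c(10, 10, 6))
  m[1:2, 1:2, 1:2] <- TRUE          # 8-voxel component
  m[8, 8, 5] <- TRUE                # single voxel
  out <- duofilm:::remove_small_objects(m, 8L)
  expect_equal(sum(out), 8L)
  expect_false(out[8, 8, 5])
  expect_identical(duofilm:::remove_small_objects(m, 1L), m)
})

test_that("a mismatched threshold/segment configuration is rejected", {
  st <- make_uniform_stack(0, 0)
  p <- segmentation_params(green_thresholds = c(14, 12))  # 2 thresholds
  expect_error(segment_green(st, array(FALSE, dim(st$red)), p,
                             default_depth_segments()),
               "one green threshold per depth segment")
})
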