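test_that("an empty phantom with noise off yields all-zero channels and zero volumes", {
  p <- degradation_off(small_phantom_params())
  p$n_filaments <- 0L
  p$n_rods <- 0L
  res <- generate_phantom(p)
  expect_true(all(res$stack$red == 0))
  expect_true(all(res$stack$green == 0))
  expect_true(all(res$truth$volumes$true_volume_um3 == 0))
})

test_that("capsule voxelization matches the brute-force voxel-center oracle", {
  dims <- c(20, 20, 12)
  spacing <- c(0.5, 0.5, 1)   # (dy, dx, dz)
  cases <- list(
    # straight axis-aligned cylinder, radius two lateral voxels
    list(a = c(5, 2, 6), b = c(5, 8, 6), r = 1.0),
    # oblique capsule
    list(a = c(2.3, 3.1, 2.2), b = c(7.7, 6.2, 9.5), r = 1.4),
    # degenerate segment (sphere)
    list(a = c(5, 5, 6), b = c(5, 5, 6), r = 2.1)
  )
  for (cs in cases) {
    got <- duofilm:::mark_capsule(array(FALSE, dims), cs$a, cs$b, cs$r, spacing)
    want <- oracle_capsule_mask(dims, spacing, cs$a, cs$b, cs$r)
    expect_identical(got, want)
  }
})

test_that("straight-cylinder truth volume equals the oracle count times voxel volume", {
  dims <- c(20, 20, 12); spacing <- c(0.5, 0.5, 1)
  a <- c(5, 1, 6); b <- c(5, 9, 6); r <- 1.0
  mask <- duofilm:::mark_capsule(array(FALSE, dims), a, b, r, spacing)
  oracle_count <- sum(oracle_capsule_mask(dims, spacing, a, b, r))
  expect_equal(sum(mask) * prod(spacing), oracle_count * prod(spacing))
})

test_that("phantom generation is bit-identical under a fixed seed", {
  p <- small_phantom_params(seed = 11L)
  r1 <- generate_phantom(p)
  r2 <- generate_phantom(p)
  expect_identical(r1$stack$red, r2$stack$red)
  expect_identical(r1$stack$green, r2$stack$green)
  expect_identical(r1$truth$red_truth, r2$truth$red_truth)
  r3 <- generate_phantom(small_phantom_params(seed = 12L))
  expect_false(identical(r1$stack$red, r3$stack$red))
})

test_that("ground truth is invariant to the noise parameters", {
  p1 <- small_phantom_params(seed = 5L)
  p2 <- small_phantom_params(seed = 5L, gauss_noise_sd = 20,
                             poisson_scale = 0.25)
  r1 <- generate_phantom(p1)
  r2 <- generate_phantom(p2)
  expect_identical(r1$truth$red_truth, r2$truth$red_truth)
  expect_identical(r1$truth$green_truth, r2$truth$green_truth)
  expect_equal(r1$truth$volumes, r2$truth$volumes)
})

test_that("with seeding fraction 1 every rod centroid lies in the seeding layer", {
  for (seed in 1:3) {
    p <- small_phantom_params(seed = seed, seeding_layer_fraction = 1)
    res <- generate_phantom(p)
    expect_true(all(res$truth$rods$z < p$seeding_depth))
  }
})

test_that("with coloc fraction 1 every rod centroid lies within coloc_radius of a filament axis", {
  p <- small_phantom_params(seed = 3L, coloc_fraction = 1, n_rods = 40)
  res <- generate_phantom(p)
  rods <- res$truth$rods
  for (i in seq_len(nrow(rods))) {
    d <- min(vapply(res$truth$filament_axes, function(ax) {
      oracle_dist_to_polyline(c(rods$y[i], rods$x[i], rods$z[i]), ax)
    }, numeric(1)))
    expect_lte(d, p$coloc_radius + 1e-9)
  }
})

test_that("requesting co-localized rods without filaments errors", {
  p <- small_phantom_params(n_filaments = 0, coloc_fraction = 0.5)
  expect_error(generate_phantom(p), "filament")
})

test_that("mean in-mask intensity decreases with distance from the detector side", {
  # uniform slab truth, attenuation only: slice means must increase with z
  p <- degradation_off(small_phantom_params())
  p$attenuation_length <- 20
  truth <- array(TRUE, dim = c(8, 8, 16))
  p$voxel_spacing <- c(1, 0.5, 0.5)
  img <- duofilm:::degrade_channel(truth, 200, p)
  slice_means <- apply(img, 3, mean)
  expect_true(all(diff(slice_means) >= 0))
  expect_gt(slice_means[16], slice_means[1])
})

test_that("phantom parameter validation rejects unresolvable geometry", {
  expect_error(phantom_params(grid_shape = c(0, 10, 10)), "grid_shape")
  expect_error(phantom_params(rod_radius = 0.1), "half a voxel")
  expect_error(phantom_params(psf_sigma = c(0.1, 0.1, 0.1)), "half a voxel")
  expect_error(phantom_params(coloc_fraction = 1.2), "\\[0, 1\\]")
  expect_silent(phantom_params(psf_sigma = c(0, 0, 0)))
})

test_that("time series scale object counts deterministically (half-up rounding)", {
  base <- degradation_off(small_phantom_params(seed = 2L))
  base$n_rods <- 10L
  base$n_filaments <- 1L
  base$coloc_fraction <- 0

  flat <- generate_timeseries(base, 3, growth = list(filament = 1, rod = 1))
  expect_equal(vapply(flat, function(d) d$truth$params$n_rods, integer(1)),
               c(10L, 10L, 10L))

  doubling <- generate_timeseries(base, 3, growth = list(filament = 1, rod = 2))
  expect_equal(vapply(doubling, function(d) d$truth$params$n_rods, integer(1)),
               c(10L, 20L, 40L))
  # derived per-day seeds
  expect_equal(vapply(doubling, function(d) d$truth$params$seed, integer(1)),
               base$seed + 10007L * (0:2))

  frac <- generate_timeseries(base, 3, growth = list(filament = 1, rod = 1.3))
  expect_equal(frac[[3]]$truth$params$n_rods, 17L)  # round(16.9) half-up

  expect_error(generate_timeseries(base, 3, growth = list(rod = -1)), ">= 0")
  expect_error(generate_timeseries(base, 0), ">= 1")
})
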