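# Shared fixtures: small phantoms and random stacks built in code.

# a fast phantom: same structure as the defaults, smaller field
small_phantom_params <- function(..., seed = 1L) {
  args <- utils::modifyList(
    list(grid_shape = c(24, 48, 48), voxel_spacing = c(1, 0.5, 0.5),
         n_filaments = 1, filament_n_steps = 15, n_rods = 60, seed = seed),
    list(...)
  )
  do.call(phantom_params, args)
}

noise_off <- function(params) {
  params$gauss_noise_sd <- 0
  params$poisson_scale <- 0
  params
}

degradation_off <- function(params) {
  params <- noise_off(params)
  params$psf_sigma <- c(0, 0, 0)
  params$attenuation_length <- Inf
  params
}

# random two-channel stack with intensities on the 8-bit scale
random_stack <- function(dims = c(16, 16, 12), spacing = c(2, 1, 1),
                         max_intensity = 255) {
  image_stack(
    red = array(runif(prod(dims), 0, max_intensity), dim = dims),
    green = array(runif(prod(dims), 0, max_intensity), dim = dims),
    voxel_spacing = spacing
  )
}

# brute-force voxelization oracle: all voxel centers within `radius`
# of the segment [a, b] (physical y/x/z coords, spacing in y/x/z order)
oracle_capsule_mask <- function(dims, spacing_yxz, a, b, radius) {
  out <- array(FALSE, dim = dims)
  v <- b - a
  vv <- sum(v^2)
  for (iy in seq_len(dims[1])) for (ix in seq_len(dims[2])) for (iz in seq_len(dims[3])) {
    c_ <- c((iy - 0.5) * spacing_yxz[1],
            (ix - 0.5) * spacing_yxz[2],
            (iz - 0.5) * spacing_yxz[3])
    if (vv == 0) {
      d2 <- sum((c_ - a)^2)
    } else {
      t <- sum((c_ - a) * v) / vv
      t <- min(max(t, 0), 1)
      d2 <- sum((c_ - (a + t * v))^2)
    }
    if (d2 <= radius^2) out[iy, ix, iz] <- TRUE
  }
  out
}

# independent point-to-polyline distance (for co-localization checks)
oracle_dist_to_polyline <- function(point, polyline) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    v <- b - a; vv <- sum(v^2)
    t <- if (vv == 0) 0 else min(max(sum((point - a) * v) / vv, 0), 1)
    best <- min(best, sqrt(sum((point - (a + t * v))^2)))
  }
  best
}

# independent quantile oracle: sort-based linear interpolation (type 7)
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
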