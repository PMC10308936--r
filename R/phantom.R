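# Synthetic two-channel confocal phantoms with voxel-level ground truth.
#
# The generator emulates the structures seen in early dual-species
# phototrophic biofilms: cyanobacterial filaments modelled as 3-D
# random-walk tubes growing from near the attachment surface toward the
# light-facing (detector) side, and heterotrophic rods modelled as
# capsules, a configurable fraction of which sit in a near-surface
# seeding layer and/or cluster around the filaments (co-localization).
# Truth masks are recorded before any optical degradation; the noisy
# channels derive from them by intensity assignment -> depth attenuation
# -> Gaussian PSF -> Poisson resampling -> additive Gaussian noise ->
# clipping/rounding to the 8-bit range.

#' Phantom generator parameters
#'
#' All lengths are in micrometres. `grid_shape` is `(nz, ny, nx)` and
#' `voxel_spacing` is `(dz, dy, dx)`, matching [image_stack()].
#' `psf_sigma` is the Gaussian PSF sigma per axis `(z, y, x)`; 0 turns
#' the PSF off, and any positive sigma (or object radius) smaller than
#' half a voxel is rejected as unresolvable. `attenuation_length` is the
#' exponential decay length of intensity with distance from the detector
#' side (the high-z face, i.e. the light-facing side of the biofilm);
#' `Inf` disables attenuation. `poisson_scale` is the number of photons
#' per intensity unit (0 disables shot noise); `gauss_noise_sd` is the
#' read-noise sigma (0 disables).
#'
#' `seeding_layer_fraction` is the fraction of rods whose centroid lies
#' in the seeding layer (z < `seeding_depth`, default 10 um);
#' `coloc_fraction` is the fraction of rods placed with centroid within
#' `coloc_radius` of a filament axis (touching, but not overlapping, the
#' filament). Remaining rods are placed away from the filaments so the
#' planted co-localized fraction is a clean ground truth.
#'
#' @param grid_shape integer `(nz, ny, nx)` voxel counts.
#' @param voxel_spacing numeric `(dz, dy, dx)` um.
#' @param n_filaments,filament_radius,filament_step,filament_step_sd,filament_n_steps
#'   filament count, tube radius, random-walk step length, Gaussian
#'   heading perturbation (um per step) and number of steps.
#' @param n_rods,rod_length,rod_radius rod count and capsule geometry
#'   (`rod_length` is end-to-end, including the hemispherical caps).
#' @param seeding_layer_fraction,seeding_depth,coloc_fraction,coloc_radius
#'   placement rules, see Details.
#' @param psf_sigma numeric `(z, y, x)` um.
#' @param attenuation_length um; `Inf` = none.
#' @param red_intensity,green_intensity emitted intensity (8-bit scale).
#' @param gauss_noise_sd,poisson_scale noise model, see Details.
#' @param seed integer; identical params (incl. seed) regenerate a
#'   bit-identical phantom.
#' @return A validated parameter list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(32, 96, 96),
                           voxel_spacing = c(1, 0.5, 0.5),
                           n_filaments = 2,
                           filament_radius = 2,
                           filament_step = 2,
                           filament_step_sd = 0.5,
                           filament_n_steps = 30,
                           n_rods = 400,
                           rod_length = 3,
                           rod_radius = 0.6,
                           seeding_layer_fraction = 0.8,
                           seeding_depth = 10,
                           coloc_fraction = 0.4,
                           coloc_radius = 4,
                           psf_sigma = c(0.5, 0.25, 0.25),
                           attenuation_length = 150,
                           red_intensity = 180,
                           green_intensity = 150,
                           gauss_noise_sd = 5,
                           poisson_scale = 1,
                           seed = 1L) {
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_spacing = as.numeric(voxel_spacing),
            n_filaments = as.integer(n_filaments),
            filament_radius = filament_radius,
            filament_step = filament_step,
            filament_step_sd = filament_step_sd,
            filament_n_steps = as.integer(filament_n_steps),
            n_rods = as.integer(n_rods),
            rod_length = rod_length,
            rod_radius = rod_radius,
            seeding_layer_fraction = seeding_layer_fraction,
            seeding_depth = seeding_depth,
            coloc_fraction = coloc_fraction,
            coloc_radius = coloc_radius,
            psf_sigma = as.numeric(psf_sigma),
            attenuation_length = attenuation_length,
            red_intensity = red_intensity,
            green_intensity = green_intensity,
            gauss_noise_sd = gauss_noise_sd,
            poisson_scale = poisson_scale,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (length(p$grid_shape) != 3L || any(p$grid_shape <= 0L)) {
    stop("`grid_shape` must be three positive voxel counts (nz, ny, nx)",
         call. = FALSE)
  }
  if (length(p$voxel_spacing) != 3L || any(p$voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be three positive lengths (dz, dy, dx)",
         call. = FALSE)
  }
  for (f in c("filament_radius", "filament_step", "rod_length", "rod_radius",
              "seeding_depth", "coloc_radius", "red_intensity",
              "green_intensity", "poisson_scale")) {
    if (p[[f]] < 0) stop(sprintf("`%s` must be non-negative", f), call. = FALSE)
  }
  for (f in c("filament_radius", "filament_step", "rod_length", "rod_radius",
              "seeding_depth", "coloc_radius")) {
    if (p[[f]] <= 0) stop(sprintf("`%s` must be strictly positive", f),
                          call. = FALSE)
  }
  for (f in c("seeding_layer_fraction", "coloc_fraction")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
    }
  }
  half_vox <- max(p$voxel_spacing) / 2
  if (p$n_filaments > 0L && p$filament_radius < half_vox) {
    stop("`filament_radius` below half a voxel: unresolvable geometry",
         call. = FALSE)
  }
  if (p$n_rods > 0L && p$rod_radius < half_vox) {
    stop("`rod_radius` below half a voxel: unresolvable geometry",
         call. = FALSE)
  }
  psf <- p$psf_sigma
  if (length(psf) == 1L) psf <- rep(psf, 3L)
  if (length(psf) != 3L || any(psf < 0)) {
    stop("`psf_sigma` must be three non-negative sigmas (z, y, x)",
         call. = FALSE)
  }
  if (any(psf > 0 & psf < p$voxel_spacing / 2)) {
    stop("positive `psf_sigma` below half a voxel: unresolvable geometry",
         call. = FALSE)
  }
  if (p$attenuation_length <= 0) {
    stop("`attenuation_length` must be positive (use Inf for none)",
         call. = FALSE)
  }
  if (p$gauss_noise_sd < 0) stop("`gauss_noise_sd` must be >= 0", call. = FALSE)
  invisible(p)
}

# physical extent (y, x, z) of the grid in um
grid_extent <- function(p) {
  c(y = p$grid_shape[2] * p$voxel_spacing[2],
    x = p$grid_shape[3] * p$voxel_spacing[3],
    z = p$grid_shape[1] * p$voxel_spacing[1])
}

round_half_up <- function(x) floor(x + 0.5)

unit_vector <- function(v) v / sqrt(sum(v^2))

# random unit vector, optionally biased toward +z (third component)
random_direction <- function(z_bias = 0) {
  v <- rnorm(3)
  v[3] <- abs(v[3]) * (z_bias > 0) + v[3] * (z_bias <= 0) + z_bias
  unit_vector(v)
}

# Reflecting random walk: returns (n_steps + 1) x 3 matrix of axis
# vertices in physical (y, x, z) coordinates.
filament_walk <- function(p, extent) {
  r <- p$filament_radius
  lo <- pmin(c(r, r, r), extent / 2)
  hi <- extent - lo
  start <- c(runif(1, lo[1], hi[1]),
             runif(1, lo[2], hi[2]),
             runif(1, min(lo[3] + 2, hi[3]), min(lo[3] + 6, hi[3])))
  dir <- random_direction(z_bias = 0.5)
  pts <- matrix(0, nrow = p$filament_n_steps + 1L, ncol = 3L)
  pts[1L, ] <- start
  pos <- start
  for (k in seq_len(p$filament_n_steps)) {
    step <- dir * p$filament_step + rnorm(3, sd = p$filament_step_sd)
    nxt <- pos + step
    # reflect at the physical boundaries
    for (ax in 1:3) {
      if (nxt[ax] < lo[ax]) { nxt[ax] <- 2 * lo[ax] - nxt[ax]; step[ax] <- -step[ax] }
      if (nxt[ax] > hi[ax]) { nxt[ax] <- 2 * hi[ax] - nxt[ax]; step[ax] <- -step[ax] }
      nxt[ax] <- min(max(nxt[ax], lo[ax]), hi[ax])
    }
    dir <- unit_vector(step)
    pos <- nxt
    pts[k + 1L, ] <- pos
  }
  pts
}

# densify a polyline so consecutive samples are <= ds apart
densify_polyline <- function(pts, ds = 0.25) {
  if (nrow(pts) < 2L) return(pts)
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / ds))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

# Mark voxels whose center lies within `radius` of segment [a, b]
# (a capsule). Operates on a logical array in place (returns it).
mark_capsule <- function(mask, a, b, radius, spacing_yxz) {
  d <- dim(mask)
  lo_phys <- pmin(a, b) - radius
  hi_phys <- pmax(a, b) + radius
  idx <- vector("list", 3L)
  for (ax in 1:3) {
    w <- spacing_yxz[ax]
    i0 <- max(1L, ceiling(lo_phys[ax] / w + 0.5))
    i1 <- min(d[ax], floor(hi_phys[ax] / w + 0.5))
    if (i0 > i1) return(mask)
    idx[[ax]] <- i0:i1
  }
  cy <- (idx[[1]] - 0.5) * spacing_yxz[1]
  cx <- (idx[[2]] - 0.5) * spacing_yxz[2]
  cz <- (idx[[3]] - 0.5) * spacing_yxz[3]
  g <- expand.grid(y = cy, x = cx, z = cz, KEEP.OUT.ATTRS = FALSE)
  v <- b - a
  vv <- sum(v^2)
  if (vv == 0) {
    d2 <- (g$y - a[1])^2 + (g$x - a[2])^2 + (g$z - a[3])^2
  } else {
    t <- ((g$y - a[1]) * v[1] + (g$x - a[2]) * v[2] + (g$z - a[3]) * v[3]) / vv
    t <- pmin(pmax(t, 0), 1)
    d2 <- (g$y - (a[1] + t * v[1]))^2 +
          (g$x - (a[2] + t * v[2]))^2 +
          (g$z - (a[3] + t * v[3]))^2
  }
  inside <- d2 <= radius^2
  if (any(inside)) {
    sub <- mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(inside) <- dim(sub)
    mask[idx[[1]], idx[[2]], idx[[3]]] <- sub | inside
  }
  mask
}

# Sample rod placements. Returns a list with endpoint matrices and flags.
sample_rods <- function(p, axis_pts, extent) {
  n <- p$n_rods
  if (n == 0L) {
    return(list(a = matrix(0, 0, 3), b = matrix(0, 0, 3),
                centroid = matrix(0, 0, 3),
                coloc = logical(0), seeded = logical(0)))
  }
  n_coloc <- round_half_up(p$coloc_fraction * n)
  n_seed <- round_half_up(p$seeding_layer_fraction * n)
  if (n_coloc > 0L && (is.null(axis_pts) || nrow(axis_pts) == 0L)) {
    stop("coloc_fraction > 0 requires at least one filament", call. = FALSE)
  }
  coloc <- rep(FALSE, n); if (n_coloc > 0L) coloc[sample.int(n, n_coloc)] <- TRUE
  seeded <- rep(FALSE, n); if (n_seed > 0L) seeded[sample.int(n, n_seed)] <- TRUE

  half_axis <- max(p$rod_length / 2 - p$rod_radius, 0)
  half_extent <- p$rod_length / 2
  # exclusion distance keeping non-co-localized rods clear of the
  # filaments out to the default co-localization scoring radius (5 um)
  excl <- p$filament_radius + 5 + half_extent
  seed_hi <- min(p$seeding_depth, extent["z"])

  a <- matrix(0, n, 3); b <- matrix(0, n, 3); centroid <- matrix(0, n, 3)
  have_fil <- !is.null(axis_pts) && nrow(axis_pts) > 0L
  low_axis <- if (have_fil) axis_pts[axis_pts[, 3] < seed_hi, , drop = FALSE] else NULL

  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      if (coloc[i]) {
        cand <- if (seeded[i] && nrow(low_axis) > 0L) low_axis else axis_pts
        anchor <- cand[sample.int(nrow(cand), 1L), ]
        u <- random_direction()
        r_off <- p$coloc_radius * runif(1)^(1 / 3)
        cen <- anchor + u * r_off
      } else {
        zr <- if (seeded[i]) c(half_extent, max(seed_hi - 1e-9, half_extent))
              else c(min(p$seeding_depth, extent["z"] - half_extent), extent["z"] - half_extent)
        cen <- c(runif(1, half_extent, extent["y"] - half_extent),
                 runif(1, half_extent, extent["x"] - half_extent),
                 runif(1, zr[1], zr[2]))
      }
      dir <- random_direction()
      e1 <- cen - dir * half_axis
      e2 <- cen + dir * half_axis
      pts3 <- rbind(e1, cen, e2)
      if (any(pts3 < 0) || any(t(pts3) > extent[c("y", "x", "z")])) next
      if (seeded[i] && cen[3] >= p$seeding_depth) next
      if (have_fil) {
        dmin <- min(min_dist_to_points(pts3, axis_pts))
        if (coloc[i]) {
          # touching but not overlapping the filament tube
          if (dmin <= p$filament_radius + p$rod_radius) next
          cen_d <- min_dist_to_points(matrix(cen, 1), axis_pts)
          if (cen_d > p$coloc_radius) next
        } else {
          if (dmin < excl) next
        }
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place a rod after 500 attempts; the grid is too crowded",
           call. = FALSE)
    }
    a[i, ] <- e1; b[i, ] <- e2; centroid[i, ] <- cen
  }
  list(a = a, b = b, centroid = centroid, coloc = coloc, seeded = seeded)
}

# degrade one channel: intensity -> attenuation -> PSF -> noise -> 8-bit
degrade_channel <- function(truth, intensity, p) {
  d <- dim(truth)
  img <- truth * intensity
  if (is.finite(p$attenuation_length)) {
    zc <- z_slice_centers(d[3], p$voxel_spacing[1])
    z_max <- d[3] * p$voxel_spacing[1]
    fac <- exp(-(z_max - zc) / p$attenuation_length)
    img <- sweep(img, 3L, fac, `*`)
  }
  psf <- p$psf_sigma
  if (length(psf) == 1L) psf <- rep(psf, 3L)
  if (any(psf > 0)) {
    sigma_vox <- c(psf[2] / p$voxel_spacing[2],   # y
                   psf[3] / p$voxel_spacing[3],   # x
                   psf[1] / p$voxel_spacing[1])   # z
    img <- gauss_blur_3d(img, d, sigma_vox)
  }
  if (p$poisson_scale > 0) {
    img[] <- rpois(length(img), lambda = pmax(img, 0) * p$poisson_scale) /
      p$poisson_scale
  }
  if (p$gauss_noise_sd > 0) {
    img <- img + rnorm(length(img), sd = p$gauss_noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 255))
  dim(img) <- d
  img
}

#' Generate a synthetic two-channel phantom stack with ground truth
#'
#' @param params a [phantom_params()] object.
#' @return A list with elements `stack` (an [image_stack()]) and
#'   `truth` (class `phantom_truth`: noise-free boolean masks
#'   `red_truth`/`green_truth`, the filament axes, rod placements with
#'   their co-localization/seeding flags, and per-segment true volumes
#'   for the standard depth slabs).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  validate_phantom_params(params)
  withr::with_seed(params$seed, generate_phantom_impl(params))
}

generate_phantom_impl <- function(p) {
  extent <- grid_extent(p)
  dims <- c(p$grid_shape[2], p$grid_shape[3], p$grid_shape[1])  # (ny, nx, nz)
  spacing_yxz <- p$voxel_spacing[c(2, 3, 1)]

  axes <- lapply(seq_len(p$n_filaments), function(i) filament_walk(p, extent))
  axis_pts <- if (length(axes) > 0L) {
    do.call(rbind, lapply(axes, densify_polyline))
  } else {
    matrix(0, 0, 3)
  }

  red_truth <- array(FALSE, dim = dims)
  for (pts in axes) {
    for (i in seq_len(nrow(pts) - 1L)) {
      red_truth <- mark_capsule(red_truth, pts[i, ], pts[i + 1L, ],
                                p$filament_radius, spacing_yxz)
    }
  }

  rods <- sample_rods(p, axis_pts, extent)
  green_truth <- array(FALSE, dim = dims)
  for (i in seq_len(length(rods$coloc))) {
    green_truth <- mark_capsule(green_truth, rods$a[i, ], rods$b[i, ],
                                p$rod_radius, spacing_yxz)
  }

  red <- degrade_channel(red_truth, p$red_intensity, p)
  green <- degrade_channel(green_truth, p$green_intensity, p)
  stack <- image_stack(red, green, p$voxel_spacing)

  truth <- structure(list(
    red_truth = red_truth,
    green_truth = green_truth,
    filament_axes = axes,
    rods = tibble::tibble(
      y = rods$centroid[, 1], x = rods$centroid[, 2], z = rods$centroid[, 3],
      coloc = rods$coloc, seeded = rods$seeded
    ),
    voxel_spacing = stack$voxel_spacing,
    params = p
  ), class = "phantom_truth")
  truth$volumes <- true_volumes(truth)

  list(stack = stack, truth = truth)
}

#' Per-segment true volumes of a phantom's truth masks
#'
#' Exact integer voxel counts times the voxel volume, per species and
#' depth segment (the truth is recorded before any optical degradation,
#' so these volumes do not depend on the noise settings).
#'
#' @param truth a `phantom_truth` object.
#' @param segments depth segments (default the standard 0-10/10-20/20-30).
#' @return tibble with `species`, `z_lo`, `z_hi`, `true_volume_um3`.
#' @export
true_volumes <- function(truth, segments = default_depth_segments()) {
  stopifnot(inherits(truth, "phantom_truth"))
  sp <- truth$voxel_spacing
  vv <- voxel_volume(sp)
  nz <- dim(truth$red_truth)[3]
  seg_idx <- slice_segment_index(nz, sp["dz"], segments)
  rows <- list()
  for (species in c("red", "green")) {
    m <- truth[[paste0(species, "_truth")]]
    for (s in seq_len(nrow(segments))) {
      slices <- which(seg_idx == s)
      cnt <- if (length(slices) > 0L) sum(m[, , slices, drop = FALSE]) else 0L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species = species,
        z_lo = segments$z_lo[s], z_hi = segments$z_hi[s],
        true_volume_um3 = cnt * vv
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a deterministic phantom time series
#'
#' Day `d` (days are numbered 0, 1, ..., `n_days` - 1) uses object
#' counts `round(base_count * multiplier^d)` (half-up) and the derived
#' seed `base_seed + 10007 * d`, so a series is fully reproducible from
#' the base parameters.
#'
#' @param base a [phantom_params()] object.
#' @param n_days number of days (>= 1).
#' @param growth list with per-day multipliers `filament` and `rod`
#'   (both >= 0).
#' @return list of per-day results, each as returned by
#'   [generate_phantom()] plus a `day` element.
#' @export
generate_timeseries <- function(base, n_days,
                                growth = list(filament = 1, rod = 1)) {
  stopifnot(inherits(base, "phantom_params"))
  n_days <- as.integer(n_days)
  if (n_days < 1L) stop("`n_days` must be >= 1", call. = FALSE)
  mf <- growth$filament %||% 1
  mr <- growth$rod %||% 1
  if (mf < 0 || mr < 0) stop("growth multipliers must be >= 0", call. = FALSE)
  lapply(seq_len(n_days) - 1L, function(day) {
    p <- base
    p$n_filaments <- as.integer(round_half_up(base$n_filaments * mf^day))
    p$n_rods <- as.integer(round_half_up(base$n_rods * mr^day))
    p$seed <- as.integer(base$seed + 10007L * day)
    res <- generate_phantom(p)
    res$day <- day
    res
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
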