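# Spatially resolved fluorescence-intensity analysis: lateral profiles,
# whole-image intensities, co-localization and retention scores.

#' Lateral fluorescence-intensity profile
#'
#' For each position along one lateral axis, the mean intensity of each
#' channel over the orthogonal lateral axis and the chosen z range
#' (voxel-center membership, half-open interval).
#'
#' @param stack an [image_stack()].
#' @param axis `"x"` or `"y"`: the axis the profile runs along.
#' @param z_range numeric `c(lo, hi)` in um, or a one-row depth-segment
#'   data frame.
#' @return tibble with `position_um`, `red_intensity`, `green_intensity`.
#' @export
lateral_profile <- function(stack, axis = c("x", "y"), z_range) {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  if (is.data.frame(z_range)) z_range <- c(z_range$z_lo[1], z_range$z_hi[1])
  if (length(z_range) != 2L || z_range[2] <= z_range[1]) {
    stop("`z_range` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  sp <- stack$voxel_spacing
  d <- dim(stack$red)
  zc <- z_slice_centers(d[3], sp["dz"])
  slices <- which(zc >= z_range[1] & zc < z_range[2])
  if (length(slices) == 0L) {
    stop("empty z range: no voxel centers fall inside it", call. = FALSE)
  }
  profile_one <- function(img) {
    sub <- img[, , slices, drop = FALSE]
    if (axis == "x") {
      # mean over y and z for each x column
      apply(sub, 2, mean)
    } else {
      apply(sub, 1, mean)
    }
  }
  n_pos <- if (axis == "x") d[2] else d[1]
  step <- if (axis == "x") sp["dx"] else sp["dy"]
  tibble::tibble(
    position_um = (seq_len(n_pos) - 0.5) * step,
    red_intensity = profile_one(stack$red),
    green_intensity = profile_one(stack$green)
  )
}

#' Whole-image mean intensity per channel
#' @param stack an [image_stack()].
#' @return named numeric `c(red_mean, green_mean)`.
#' @export
whole_image_intensity <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  c(red_mean = mean(stack$red), green_mean = mean(stack$green))
}

# physical-unit distance (um) of every voxel center to the nearest
# true voxel of `mask`; Inf everywhere when the mask is empty
distance_to_mask <- function(mask, spacing) {
  m <- as_mask_array(mask)
  spacing <- setNames(as.numeric(spacing), c("dz", "dy", "dx"))
  d2 <- edt_sq_3d(m, dim(m), c(spacing["dy"], spacing["dx"], spacing["dz"]))
  sqrt(d2)
}

#' Co-localization fraction of the green mask around the red mask
#'
#' Fraction of true green voxels whose voxel-center Euclidean distance
#' (physical um, exact distance transform) to the red mask is at most
#' `radius`. An empty green mask yields fraction 0 with
#' `green_empty = TRUE`; an empty red mask yields fraction 0.
#'
#' @param green_mask,red_mask masks of identical shape.
#' @param radius um (default 5, about one rod length).
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @return list with `radius`, `green_coloc_fraction`,
#'   `n_green_voxels`, `green_empty`.
#' @export
coloc_fraction <- function(green_mask, red_mask, radius = 5, spacing) {
  g <- as_mask_array(green_mask)
  r <- as_mask_array(red_mask)
  if (!identical(dim(g), dim(r))) {
    stop("green and red mask shapes differ", call. = FALSE)
  }
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  n_green <- sum(g)
  if (n_green == 0L) {
    return(list(radius = radius, green_coloc_fraction = 0,
                n_green_voxels = 0L, green_empty = TRUE))
  }
  dist <- distance_to_mask(r, spacing)
  frac <- mean(dist[g] <= radius)
  list(radius = radius, green_coloc_fraction = frac,
       n_green_voxels = n_green, green_empty = FALSE)
}

#' Retention of co-localized vs non-co-localized green voxels
#'
#' Splits the green voxels of the "before" time point into those within
#' `radius` of the before red mask (co-localized) and the rest, and
#' reports the fraction of each class still green in the "after" time
#' point. Grids must be aligned (equal shapes); registration of real
#' time points is out of scope, phantom pairs are generated aligned.
#'
#' @param before list with `red` and `green` masks.
#' @param after list with at least a `green` mask.
#' @param radius um.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @return list with `retained_coloc_fraction`,
#'   `retained_noncoloc_fraction`, `n_coloc`, `n_noncoloc` (fractions
#'   are NA for empty classes; both 0 when the after green mask is
#'   empty and the class is not).
#' @export
retention_analysis <- function(before, after, radius = 5, spacing) {
  gb <- as_mask_array(before$green)
  rb <- as_mask_array(before$red)
  ga <- as_mask_array(after$green)
  if (!identical(dim(gb), dim(rb)) || !identical(dim(gb), dim(ga))) {
    stop("before/after grids are misaligned (shapes differ)", call. = FALSE)
  }
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  dist <- distance_to_mask(rb, spacing)
  coloc_class <- gb & dist <= radius
  noncoloc_class <- gb & dist > radius
  frac <- function(cls) {
    n <- sum(cls)
    if (n == 0L) NA_real_ else sum(ga[cls]) / n
  }
  list(retained_coloc_fraction = frac(coloc_class),
       retained_noncoloc_fraction = frac(noncoloc_class),
       n_coloc = sum(coloc_class),
       n_noncoloc = sum(noncoloc_class))
}
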