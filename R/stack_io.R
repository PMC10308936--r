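# Image stacks, depth segments, and all file I/O (TIFF + sidecar, CSV).
#
# Conventions (documented, load-bearing):
#  * arrays have dim = c(ny, nx, nz); slice k is the k-th optical section
#  * z = 0 is the attachment surface; slice k spans [ (k-1)*dz, k*dz )
#    and its voxel centers sit at (k - 0.5)*dz
#  * voxel_spacing is a length-3 vector in micrometres, order (dz, dy, dx)
#  * intensities are stored on the 8-bit scale (0-255)

#' Construct a two-channel image stack
#'
#' @param red,green 3-D numeric arrays of identical dimension
#'   `c(ny, nx, nz)` holding non-negative intensities (8-bit scale).
#' @param voxel_spacing numeric length-3, micrometres per voxel in order
#'   `(dz, dy, dx)`. z = 0 is the attachment surface; z grows away from it.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(red, green, voxel_spacing) {
  if (!is.array(red) || length(dim(red)) != 3L) {
    stop("`red` must be a 3-D array", call. = FALSE)
  }
  if (!is.array(green) || length(dim(green)) != 3L) {
    stop("`green` must be a 3-D array", call. = FALSE)
  }
  if (!identical(dim(red), dim(green))) {
    stop("red and green channels must have identical dimensions", call. = FALSE)
  }
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be three strictly positive values (dz, dy, dx)",
         call. = FALSE)
  }
  if (any(red < 0) || any(green < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(red = red, green = green,
         voxel_spacing = setNames(voxel_spacing, c("dz", "dy", "dx"))),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$red)
  sp <- x$voxel_spacing
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels (ny, nx, nz), spacing %.3g/%.3g/%.3g um (dz/dy/dx)\n",
    d[1], d[2], d[3], sp["dz"], sp["dy"], sp["dx"]))
  invisible(x)
}

# physical z coordinate of each slice's voxel centers
z_slice_centers <- function(nz, dz) (seq_len(nz) - 0.5) * dz

voxel_volume <- function(spacing) prod(spacing)

#' Define depth segments
#'
#' Depth segments are half-open z-slabs `[z_lo, z_hi)` measured in
#' micrometres from the attachment surface. A voxel belongs to the
#' segment containing its center.
#'
#' @param breaks increasing numeric vector of slab boundaries, or a
#'   data frame already holding `z_lo`/`z_hi` columns.
#' @return A tibble with columns `z_lo`, `z_hi`.
#' @export
depth_segments <- function(breaks) {
  if (is.data.frame(breaks)) {
    stopifnot(all(c("z_lo", "z_hi") %in% names(breaks)))
    seg <- tibble::tibble(z_lo = as.numeric(breaks$z_lo),
                          z_hi = as.numeric(breaks$z_hi))
  } else {
    breaks <- as.numeric(breaks)
    if (length(breaks) < 2L) stop("need at least two break points", call. = FALSE)
    seg <- tibble::tibble(z_lo = breaks[-length(breaks)], z_hi = breaks[-1])
  }
  if (any(seg$z_hi <= seg$z_lo)) {
    stop("each segment needs z_lo < z_hi", call. = FALSE)
  }
  o <- order(seg$z_lo)
  seg <- seg[o, ]
  if (nrow(seg) > 1L && any(seg$z_lo[-1] < seg$z_hi[-nrow(seg)])) {
    stop("depth segments must be disjoint", call. = FALSE)
  }
  seg
}

#' The standard three analysis slabs: 0-10, 10-20, 20-30 um
#' @export
default_depth_segments <- function() depth_segments(c(0, 10, 20, 30))

# segment index (NA if none) for each slice center
slice_segment_index <- function(nz, dz, segments) {
  zc <- z_slice_centers(nz, dz)
  idx <- rep(NA_integer_, nz)
  for (s in seq_len(nrow(segments))) {
    hit <- zc >= segments$z_lo[s] & zc < segments$z_hi[s]
    idx[hit] <- s
  }
  idx
}

#' Write a two-channel stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are channel-interleaved in z order: red slice 1, green slice 1,
#' red slice 2, ... The sidecar (`<path>.json`) records the layout,
#' voxel spacing and any extra metadata, and is what [read_stack()]
#' uses to restore the stack.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param metadata named list merged into the sidecar (e.g. seed, params).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = list()) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$red)[3]
  pages <- vector("list", 2L * nz)
  for (k in seq_len(nz)) {
    pages[[2L * k - 1L]] <- pmin(pmax(stack$red[, , k], 0), 255) / 255
    pages[[2L * k]] <- pmin(pmax(stack$green[, , k], 0), 255) / 255
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- c(list(
    format = "duofilm-stack",
    shape = unname(dim(stack$red)),        # (ny, nx, nz)
    n_slices = nz,
    channels = c("red", "green"),
    page_order = "channel_interleaved",
    voxel_spacing_um = unname(stack$voxel_spacing),  # (dz, dy, dx)
    z_origin = "attachment_surface_first_slice"
  ), metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a two-channel stack written by [write_stack()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @param spacing_override optional length-3 numeric `(dz, dy, dx)` that
#'   takes precedence over the sidecar spacing; required when no sidecar
#'   is present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("stack file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  if (length(pages) < 2L || length(pages) %% 2L != 0L) {
    stop("green channel not found: expected channel-interleaved pages (2 per slice)",
         call. = FALSE)
  }
  nz <- length(pages) %/% 2L
  d <- dim(pages[[1]])
  red <- array(0, dim = c(d[1], d[2], nz))
  green <- array(0, dim = c(d[1], d[2], nz))
  for (k in seq_len(nz)) {
    red[, , k] <- pages[[2L * k - 1L]]
    green[, , k] <- pages[[2L * k]]
  }
  spacing <- spacing_override
  if (is.null(spacing) && !is.null(sidecar$voxel_spacing_um)) {
    spacing <- sidecar$voxel_spacing_um
  }
  if (is.null(spacing)) {
    stop("voxel spacing not available: no sidecar and no `spacing_override`",
         call. = FALSE)
  }
  image_stack(red, green, spacing)
}

#' Write a boolean mask as an 8-bit (0/255) multi-page TIFF
#' @param mask logical 3-D array or [segmentation_mask].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_array(mask)
  pages <- lapply(seq_len(dim(m)[3]), function(k) (m[, , k]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a mask TIFF written by [write_mask()]
#' @param path mask TIFF path.
#' @return logical 3-D array.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("mask file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  m <- array(FALSE, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) m[, , k] <- pages[[k]] > 127
  m
}

biovolume_csv_columns <- c(
  "condition", "day", "replicate", "species",
  "segment_lo_um", "segment_hi_um",
  "cell_volume_um3", "segment_volume_um3", "biovolume_percent"
)

#' Write biovolume records to CSV
#'
#' One row per (condition, day, replicate, species, depth segment), in
#' that deterministic sort order.
#'
#' @param records tibble of biovolume records (see [biovolume_records()]).
#' @param path output CSV path.
#' @export
write_quantification_csv <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records to write", call. = FALSE)
  }
  missing_cols <- setdiff(biovolume_csv_columns, names(records))
  if (length(missing_cols) > 0L) {
    stop(sprintf("records are missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- records[, biovolume_csv_columns]
  out <- out[order(out$condition, out$day, out$replicate,
                   out$species, out$segment_lo_um), ]
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a CSV written by [write_quantification_csv()]
#' @param path CSV path.
#' @export
read_quantification_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    condition = readr::col_character(),
                    day = readr::col_integer(),
                    replicate = readr::col_character(),
                    species = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
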