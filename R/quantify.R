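# Depth-stratified biovolume, species ratios, and replicate statistics.

#' Biovolume per depth segment
#'
#' Cell volume is the count of mask voxels whose center lies in the
#' segment times the voxel volume; segment volume is the count of all
#' voxels with center in the segment times the voxel volume; the
#' biovolume percent is their ratio times 100 (the total analyzed
#' volume of each slab counts as 100%).
#'
#' @param mask `segmentation_mask` or logical 3-D array.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @param segments depth segments (half-open, um).
#' @return tibble with `z_lo`, `z_hi`, `cell_volume_um3`,
#'   `segment_volume_um3`, `biovolume_percent`.
#' @export
biovolume_by_segment <- function(mask, spacing,
                                 segments = default_depth_segments()) {
  m <- as_mask_array(mask)
  spacing <- setNames(as.numeric(spacing), c("dz", "dy", "dx"))
  d <- dim(m)
  z_extent <- d[3] * spacing["dz"]
  outside <- segments$z_hi <= 0 | segments$z_lo >= z_extent
  if (any(outside)) {
    s <- which(outside)[1]
    stop(sprintf("segment [%g, %g) lies entirely outside the stack (z extent %g um)",
                 segments$z_lo[s], segments$z_hi[s], z_extent), call. = FALSE)
  }
  vv <- voxel_volume(spacing)
  seg_idx <- slice_segment_index(d[3], spacing["dz"], segments)
  res <- lapply(seq_len(nrow(segments)), function(s) {
    slices <- which(seg_idx == s)
    cell <- if (length(slices)) sum(m[, , slices, drop = FALSE]) else 0L
    total <- length(slices) * d[1] * d[2]
    tibble::tibble(
      z_lo = segments$z_lo[s], z_hi = segments$z_hi[s],
      cell_volume_um3 = cell * vv,
      segment_volume_um3 = total * vv,
      biovolume_percent = if (total > 0L) 100 * cell / total else NA_real_
    )
  })
  dplyr::bind_rows(res)
}

#' Biovolume records with experiment metadata
#'
#' Wraps [biovolume_by_segment()] into the record layout used by
#' [write_quantification_csv()].
#'
#' @inheritParams biovolume_by_segment
#' @param condition,day,replicate,species labels for the record.
#' @export
biovolume_records <- function(mask, spacing, segments = default_depth_segments(),
                              condition, day, replicate, species) {
  bv <- biovolume_by_segment(mask, spacing, segments)
  tibble::tibble(
    condition = condition, day = as.integer(day),
    replicate = as.character(replicate), species = species,
    segment_lo_um = bv$z_lo, segment_hi_um = bv$z_hi,
    cell_volume_um3 = bv$cell_volume_um3,
    segment_volume_um3 = bv$segment_volume_um3,
    biovolume_percent = bv$biovolume_percent
  )
}

#' Green-to-red biovolume ratios per replicate
#'
#' Pairs green and red biovolume records one-to-one on
#' (condition, day, replicate, segment) and reports the ratio of their
#' biovolume percentages. Records where the red biovolume is zero are
#' flagged `undefined` (ratio `NA`); such records should be excluded
#' from summary statistics.
#'
#' @param green_records,red_records record tibbles as produced by
#'   [biovolume_records()] for the two species.
#' @return tibble keyed like the inputs with `ratio_ps_to` and
#'   `undefined`.
#' @export
ratio_ps_to <- function(green_records, red_records) {
  keys <- c("condition", "day", "replicate", "segment_lo_um", "segment_hi_um")
  g <- green_records[, c(keys, "biovolume_percent")]
  r <- red_records[, c(keys, "biovolume_percent")]
  names(g)[names(g) == "biovolume_percent"] <- "green_percent"
  names(r)[names(r) == "biovolume_percent"] <- "red_percent"
  j <- dplyr::full_join(g, r, by = keys)
  bad <- is.na(j$green_percent) | is.na(j$red_percent)
  if (any(bad)) {
    miss <- j[bad, keys]
    stop(sprintf("unpaired records for keys: %s",
                 paste(apply(miss, 1, paste, collapse = "/"), collapse = "; ")),
         call. = FALSE)
  }
  j$undefined <- j$red_percent == 0
  j$ratio_ps_to <- ifelse(j$undefined, NA_real_, j$green_percent / j$red_percent)
  n_undef <- sum(j$undefined)
  if (n_undef > 0L) {
    message(sprintf("%d ratio record(s) undefined (red biovolume = 0)", n_undef))
  }
  j
}

#' Tukey box-plot statistics
#'
#' Quartiles by linear interpolation (type 7); whiskers reach the most
#' extreme data point within 1.5 x IQR of the respective quartile;
#' values beyond the whiskers are listed as outliers.
#'
#' @param values numeric vector, length >= 1, no NAs.
#' @return list with `n`, `mean`, `sd` (NA for n = 1), `median`, `q1`,
#'   `q3`, `whisker_lo`, `whisker_hi`, `outliers`.
#' @export
box_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(values)) stop("NA values not allowed", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  in_lo <- values >= q[1] - 1.5 * iqr
  in_hi <- values <= q[3] + 1.5 * iqr
  wlo <- min(values[in_lo])
  whi <- max(values[in_hi])
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) > 1L) sd(values) else NA_real_,
       median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = wlo, whisker_hi = whi,
       outliers = sort(values[!in_lo | !in_hi]))
}

#' Welch's unequal-variance two-sample t-test (two-sided)
#'
#' Degrees of freedom by Welch-Satterthwaite. Used for the depth and
#' condition comparisons of biovolume distributions.
#'
#' @param sample_a,sample_b numeric vectors, each n >= 2, not both
#'   constant-and-equal.
#' @return list with `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  va <- var(a); vb <- var(b)
  if (va + vb == 0) {
    stop("degenerate input: both samples are constant", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(t_statistic = t_stat, degrees_of_freedom = df, p_value = p)
}

#' Ratio of two means (fold change)
#' @param mean_a,mean_b numeric scalars; `mean_b` must be > 0.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (!is.finite(mean_b) || mean_b <= 0) {
    stop("`mean_b` must be > 0", call. = FALSE)
  }
  mean_a / mean_b
}

#' @importFrom stats var
NULL
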