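# CFU accounting from track-dilution plating: colony counts to CFU/L,
# resident-to-detached ratios, and the between-condition fold.

#' Colony-forming units per litre from a plate count
#'
#' `colonies * dilution_factor / plated_volume_l`. Vectorized.
#'
#' @param colonies colony count(s), >= 0.
#' @param dilution_factor dilution factor(s), >= 1.
#' @param plated_volume_l plated volume(s) in litres, > 0.
#' @return CFU per litre.
#' @export
cfu_per_liter <- function(colonies, dilution_factor, plated_volume_l) {
  if (any(colonies < 0)) stop("`colonies` must be >= 0", call. = FALSE)
  if (any(dilution_factor < 1)) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  if (any(plated_volume_l <= 0)) {
    stop("`plated_volume_l` must be > 0", call. = FALSE)
  }
  colonies * dilution_factor / plated_volume_l
}

#' Ratio of resident to detached cell concentrations
#' @param resident,detached CFU/L; `detached` must be > 0.
#' @export
resident_detached_ratio <- function(resident, detached) {
  if (any(detached <= 0)) stop("`detached` must be > 0", call. = FALSE)
  resident / detached
}

#' Fold between two resident:detached ratios
#' @param ratio_a,ratio_b dimensionless ratios; `ratio_b` must be > 0.
#' @export
condition_fold <- function(ratio_a, ratio_b) {
  if (any(ratio_b <= 0)) stop("`ratio_b` must be > 0", call. = FALSE)
  ratio_a / ratio_b
}

#' Per-condition resident:detached summary from CFU/L means
#'
#' Takes one row per (condition, source) with mean CFU/L (and optional
#' SD) and returns the resident:detached ratio per condition. When SDs
#' are supplied the ratio's standard error is propagated to first order
#' (delta method: relative errors add in quadrature) -- an optional
#' extra; the underlying report gives only means and SDs of the inputs.
#'
#' @param means tibble/data.frame with columns `condition`, `source`
#'   (`"resident"`/`"detached"`), `mean_cfu_per_l`, optional
#'   `sd_cfu_per_l`.
#' @return tibble with `condition`, `resident_cfu_per_l`,
#'   `detached_cfu_per_l`, `ratio`, `ratio_se` (NA without SDs).
#' @export
detachment_summary <- function(means) {
  stopifnot(all(c("condition", "source", "mean_cfu_per_l") %in% names(means)))
  has_sd <- "sd_cfu_per_l" %in% names(means)
  conditions <- unique(means$condition)
  rows <- lapply(conditions, function(cond) {
    sub <- means[means$condition == cond, ]
    res <- sub[sub$source == "resident", ]
    det <- sub[sub$source == "detached", ]
    if (nrow(res) != 1L || nrow(det) != 1L) {
      stop(sprintf("condition '%s' needs exactly one resident and one detached row",
                   cond), call. = FALSE)
    }
    ratio <- resident_detached_ratio(res$mean_cfu_per_l, det$mean_cfu_per_l)
    se <- if (has_sd) {
      ratio * sqrt((res$sd_cfu_per_l / res$mean_cfu_per_l)^2 +
                     (det$sd_cfu_per_l / det$mean_cfu_per_l)^2)
    } else {
      NA_real_
    }
    tibble::tibble(condition = cond,
                   resident_cfu_per_l = res$mean_cfu_per_l,
                   detached_cfu_per_l = det$mean_cfu_per_l,
                   ratio = ratio, ratio_se = se)
  })
  dplyr::bind_rows(rows)
}

#' Reference CFU/L means for the month-long reactor cultivation
#'
#' The packaged dataset of reported mean (+/- SD) CFU/L concentrations
#' of the eGFP-tagged heterotroph in the biofilm ("resident") and the
#' flow-through ("detached") after one month of capillary-reactor
#' cultivation, under N2-fixing and nitrate-fed conditions.
#'
#' @return tibble with `condition`, `source`, `mean_cfu_per_l`,
#'   `sd_cfu_per_l`.
#' @export
cfu_reference <- function() {
  path <- system.file("extdata", "cfu_reference.csv", package = "duofilm",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    condition = readr::col_character(),
                    source = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
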