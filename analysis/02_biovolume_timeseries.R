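#!/usr/bin/env Rscript
# Depth-stratified biovolume development over an 8-day time series for
# both growth conditions, from phantom generation through segmentation
# to box statistics, species ratios, and the depth/condition
# comparisons. The cyanobacterial filaments grow day by day (faster
# with nitrate); the rod population is held roughly constant, as the
# carbon-limited heterotroph mostly redistributes rather than grows.

suppressPackageStartupMessages({
  library(duofilm)
  library(dplyr)
})

out <- "results/biovolume"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n_days <- 5L        # phantom-scale stand-in for the daily imaging series
replicates <- 3L

runs <- list(
  "N2-fixing" = list(
    params = phantom_params(seeding_layer_fraction = 0.9,
                            coloc_fraction = 0.6, seed = 1001L),
    growth = list(filament = 1.25, rod = 1.0)
  ),
  "nitrate-fed" = list(
    params = phantom_params(seeding_layer_fraction = 0.7,
                            coloc_fraction = 0.3, seed = 2002L),
    growth = list(filament = 1.4, rod = 1.0)
  )
)

records <- list(); ratios <- list()
for (cond in names(runs)) {
  r <- runs[[cond]]
  res <- run_pipeline(file.path(out, gsub("[^a-z0-9]+", "_", tolower(cond))),
                      params = r$params,
                      seg_params = matched_segmentation_params(r$params),
                      condition = cond,
                      n_days = n_days, replicates = replicates,
                      growth = r$growth)
  records[[cond]] <- res$biovolume
  ratios[[cond]] <- res$ratios
}
records <- bind_rows(records)
ratios <- bind_rows(ratios)

# box statistics per condition/day/species/segment
box_tbl <- records |>
  group_by(condition, day, species, segment_lo_um) |>
  summarise(.groups = "drop", {
    b <- box_stats(biovolume_percent)
    tibble::tibble(n = b$n, mean = b$mean, sd = b$sd, median = b$median,
                   q1 = b$q1, q3 = b$q3,
                   whisker_lo = b$whisker_lo, whisker_hi = b$whisker_hi,
                   n_outliers = length(b$outliers))
  })
readr::write_csv(box_tbl, file.path(out, "box_stats.csv"))

# filament (red) growth: mean biovolume must rise with day
red_by_day <- records |>
  filter(species == "red") |>
  group_by(condition, day) |>
  summarise(mean_percent = mean(biovolume_percent), .groups = "drop")
cat("red biovolume by day (mean %):\n")
print(as.data.frame(red_by_day), digits = 3)
for (cond in names(runs)) {
  v <- red_by_day$mean_percent[red_by_day$condition == cond]
  cat(sprintf("[%s] red biovolume monotone increasing over days: %s\n",
              cond, all(diff(v) > 0)))
}

# depth comparison (surface vs deepest slab, green) on the final day
tests <- list()
for (cond in names(runs)) {
  g <- records |> filter(condition == cond, species == "green",
                         day == n_days - 1L)
  surf <- g$biovolume_percent[g$segment_lo_um == 0]
  deep <- g$biovolume_percent[g$segment_lo_um == 20]
  tt <- welch_t_test(surf, deep)
  tests[[length(tests) + 1L]] <- tibble::tibble(
    comparison = sprintf("green 0-10 vs 20-30 um, day %d", n_days - 1L),
    condition = cond, t = tt$t_statistic, df = tt$degrees_of_freedom,
    p_value = tt$p_value)
}
# condition comparison at the surface (green, final day)
ga <- records |> filter(species == "green", day == n_days - 1L,
                        segment_lo_um == 0)
a <- ga$biovolume_percent[ga$condition == "N2-fixing"]
b <- ga$biovolume_percent[ga$condition == "nitrate-fed"]
tt <- welch_t_test(a, b)
tests[[length(tests) + 1L]] <- tibble::tibble(
  comparison = sprintf("green 0-10 um, N2-fixing vs nitrate-fed, day %d",
                       n_days - 1L),
  condition = "both", t = tt$t_statistic, df = tt$degrees_of_freedom,
  p_value = tt$p_value)
tests <- bind_rows(tests)
tests$p_adjust_bh <- p.adjust(tests$p_value, method = "BH")  # extra column
readr::write_csv(tests, file.path(out, "t_tests.csv"))
cat("\nWelch comparisons:\n"); print(as.data.frame(tests), digits = 3)
cat(sprintf("surface fold (N2-fixing / nitrate-fed, green means): %.2f\n",
            fold_change(mean(a), mean(b))))

# ratio summary
ratio_tbl <- ratios |>
  filter(!undefined) |>
  group_by(condition, day, segment_lo_um) |>
  summarise(mean_ratio = mean(ratio_ps_to), n = dplyr::n(), .groups = "drop")
readr::write_csv(ratio_tbl, file.path(out, "ratio_summary.csv"))
cat("\ngreen:red ratio at the surface slab by day:\n")
print(as.data.frame(ratio_tbl |> filter(segment_lo_um == 0)), digits = 3)
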