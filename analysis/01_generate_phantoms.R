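#!/usr/bin/env Rscript
# Generate one example phantom per growth condition, write the stacks
# (multi-page TIFF + sidecar), the truth masks, and the per-segment true
# volumes. The two conditions differ in how strongly the rods seed the
# surface and cluster around the filaments: under N2-fixing conditions
# the heterotroph attaches harder (more seeding, more co-localization)
# than under nitrate-fed conditions.

suppressPackageStartupMessages(library(duofilm))

out <- "results/phantoms"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  "N2-fixing" = phantom_params(seeding_layer_fraction = 0.9,
                               coloc_fraction = 0.6, seed = 101L),
  "nitrate-fed" = phantom_params(seeding_layer_fraction = 0.7,
                                 coloc_fraction = 0.3, seed = 202L)
)

volumes <- list()
for (cond in names(conditions)) {
  p <- conditions[[cond]]
  res <- generate_phantom(p)
  slug <- gsub("[^a-z0-9]+", "_", tolower(cond))
  write_stack(res$stack, file.path(out, paste0(slug, "_stack.tif")),
              metadata = list(condition = cond, seed = p$seed))
  write_mask(res$truth$red_truth, file.path(out, paste0(slug, "_red_truth.tif")))
  write_mask(res$truth$green_truth, file.path(out, paste0(slug, "_green_truth.tif")))
  tv <- res$truth$volumes
  tv$condition <- cond
  volumes[[cond]] <- tv

  cat(sprintf("[%s] %d filaments, %d rods; whole-image intensity red %.1f / green %.1f\n",
              cond, p$n_filaments, p$n_rods,
              whole_image_intensity(res$stack)["red_mean"],
              whole_image_intensity(res$stack)["green_mean"]))
}

volumes <- do.call(rbind, volumes)
readr::write_csv(volumes, file.path(out, "true_volumes.csv"))
cat(sprintf("wrote stacks, truth masks and %s\n",
            file.path(out, "true_volumes.csv")))
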