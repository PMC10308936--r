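# duofilm

Quantification of spatial organization in dual-species phototrophic
biofilms from two-channel confocal z-stacks.

Early biofilms of a filamentous N2-fixing cyanobacterium (imaged through
its chlorophyll/phycocyanin autofluorescence, red channel) and an
eGFP-tagged heterotrophic *Pseudomonas* rod (green channel) organize in a
characteristic way: the rods form a seeding layer directly on the
attachment surface, cluster around the cyanobacterial filaments, and the
co-localized rods resist shear-driven wash-out. `duofilm` implements the
full quantification chain for this system, for microbial-ecology and
biofilm-reactor groups who want the workflow scripted and tested rather
than driven through GUI tools:

* **Phantoms** — synthetic two-channel stacks with voxel-level ground
  truth: random-walk filament tubes, capsule rods with planted
  seeding-layer and co-localization fractions, then depth attenuation,
  Gaussian PSF, Poisson shot noise and Gaussian read noise.
* **Segmentation** — isosurface-style threshold masks: the red channel at
  a single quality threshold (default `> 30`), the green channel *after*
  zeroing every voxel inside the red mask (the overestimation guard), with
  per-depth-slab thresholds (defaults 14/12/10 for 0–10/10–20/20–30 µm),
  Gaussian pre-smoothing and 26-connected small-object removal.
* **Quantification** — per-slab biovolume percent
  (100 × cell volume / slab volume), green:red ratios per replicate, Tukey
  box statistics, Welch t-tests, fold changes.
* **Profiles** — lateral intensity profiles, whole-image intensities,
  distance-transform co-localization scores, and retention of co-localized
  vs loose cells across aligned time points.
* **Proteomics** — within-sample abundance ranking (rank 1 = most
  abundant), per-condition rank means ± SD, ND/condition-exclusive calls,
  and synthetic two-condition tables with planted exclusives.
* **Detachment** — CFU/L from track-dilution plate counts and
  resident:detached ratio folds between growth conditions.

## Worked example

Generate a phantom under the default study conditions, segment both
channels with parameters matched to the generator's intensity model, and
quantify biovolume per depth slab:

```r
library(duofilm)

p     <- phantom_params(seed = 1)        # 48 x 48 x 32 um field
res   <- generate_phantom(p)             # $stack (image_stack), $truth
sp    <- matched_segmentation_params(p)
red   <- segment_red(res$stack, sp)
green <- segment_green(res$stack, red, sp)

rbind(cbind(species = "red",   biovolume_by_segment(red,   res$stack$voxel_spacing)),
      cbind(species = "green", biovolume_by_segment(green, res$stack$voxel_spacing)))
#>   species z_lo z_hi cell_volume_um3 segment_volume_um3 biovolume_percent
#> 1     red    0   10           317.8              23040             1.379
#> 2     red   10   20          1117.8              23040             4.851
#> 3     red   20   30           110.0              23040             0.477
#> 4   green    0   10           892.0              23040             3.872
#> 5   green   10   20           128.0              23040             0.556
#> 6   green   20   30            84.8              23040             0.368
```

The green species dominates the 0–10 µm surface slab (3.9% vs 0.4% in the
deepest slab — the seeding layer), while the red filaments peak in the
mid slab; every estimate here is within 0.8% of the phantom's ground
truth. The co-localization score on the same field:

```r
coloc_fraction(green, red, radius = 5,
               spacing = res$stack$voxel_spacing)$green_coloc_fraction
#> [1] 0.370    # planted rod co-localization fraction: 0.4
```

The numbered scripts under `analysis/` run the full study at phantom
scale — time-series biovolume with box statistics and Welch comparisons
(`02`), wash-out retention and intensity profiles (`03`), proteome
ranking with planted exclusive recovery (`04`), and CFU accounting
(`05`) — writing their tables under `results/`.

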