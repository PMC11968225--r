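# implantquant

Spatial image quantification and morphometry for long-term **microporous
annealed particle (MAP) scaffold** implants — injectable slurries of ~70 µm
hydrogel microparticles annealed into a porous implant, optionally containing
a ~10% subpopulation of heparin "µisland" particles that sequester endogenous
growth factors. The package is aimed at researchers quantifying the foreign
body response and tissue integration of such implants from immunofluorescence
sections and caliper measurements.

## What it computes

Given multi-channel section images (one grayscale plane per stain, known µm
pixel size) and caliper tables, the package implements:

- **ROI derivation** from the DAPI channel (smooth → threshold → close →
  fill → largest component).
- **Concentric depth-band profiles**: the ROI is partitioned by the Euclidean
  distance transform into 100 µm shells measured inward from the implant
  edge; each stain is thresholded inside the ROI and the fraction of positive
  pixels is reported per band. Bands tile the ROI exactly, so area-weighted
  band fractions reconstruct the whole-ROI fraction identically.
- **Core/outer segmentation**: the cutoff depth d at which the eroded core
  holds 50% of the implant area (for a disk of radius R, d = R(1 − 1/√2));
  thresholded objects (CD31⁺ vessels, CD31⁺Podo⁺ lymphatics) are counted per
  region and normalized to area.
- **Spot-based phenotyping**: nuclear-scale spot detection per channel,
  greedy 8 µm deduplication, then distance rules — a cell is a macrophage if
  a CD68 spot lies < 8 µm away, M1/M2 if additionally iNOS/Arg1 < 8 µm,
  T cell/T helper via CD3e/CD4, fibroblast if within 2 µm of a TE-7 surface,
  proliferating if a Ki67 spot effectively overlaps (≤ 4 µm).
- **Morphometry**: implant volume V = π/6·l·w·h from calipers and
  per-implant volume/height fold changes relative to implantation.
- **Distance-trend statistics**: a linear mixed model

  `fraction ~ group * timepoint * distance + (1 | mouse) + (1 | image)`

  fit by REML, with marginal distance slopes per group × timepoint
  (Satterthwaite intervals) and Tukey-adjusted pairwise slope contrasts.

A first-class **synthetic-scene generator** produces implant images, particle
scaffolds and caliper series with known ground truth (radial cell-density
gradients, configurable marker probabilities, 69.7 ± 2.25 µm heparin /
68.8 ± 1.87 µm plain particle size distributions, a 0.45 volume fold at 12
months), so every stage is testable without the original study images.

## Worked example

```r
library(implantquant)

cfg     <- scene_config(seed = 7)                 # default synthetic section
roi     <- make_roi(cfg)
truth   <- generate_cells(cfg, roi)
img     <- render_scene(generate_scaffold(cfg, roi), truth, cfg, roi = roi)

implant <- derive_roi(img$channels$DAPI, cfg$pixel_size_um)
implant
#> <roi_mask> 560 x 560 px at 2 um/px; area 0.7842 mm^2

inner_outer_split(implant)
#> <region_split> cutoff depth 145.0 um; inner fraction 0.500

dapi <- threshold_channel(img$channels$DAPI, implant, "otsu", stain = "DAPI")
band_profile(dapi, band_map(implant, 100))[, c("band", "mid_depth_um",
                                               "fraction_positive")]
#>   band mid_depth_um fraction_positive
#> 1    1           50            0.0365
#> 2    2          150            0.0347
#> 3    3          250            0.0287
#> 4    4          350            0.0246
#> 5    5          450            0.0180

pc <- phenotype_image(img, implant)
pc$frac_macrophage
#> [1] 0.3480826      # configured class fraction: 0.30
```

The ROI is a ~0.78 mm² disk; the 50%-area cutoff depth (145 µm) matches the
disk closed form 500·(1 − 1/√2) ≈ 146 µm to within a pixel. The DAPI band
profile falls from 3.7% positive pixels at the edge to 1.8% in the core,
reflecting the configured negative cell-density gradient; one section is
Poisson-noisy, and the mixed model is what pools sections, mice and groups
into distance slopes. The phenotyping cascade recovers the configured 30%
macrophage fraction within its documented ±0.05 tolerance.

Caliper morphometry on the default 12-month decay configuration:

```r
cal <- generate_caliper_series(caliper_series_config(seed = 7))
s <- summary(fold_change(cal))
s[s$timepoint == 12, c("group", "volume_fold_mean", "volume_pct_change")]
#>    group volume_fold_mean volume_pct_change
#> 5    Hep            0.458             -54.2
#> 10 NoHep            0.547             -45.3
```

i.e. roughly half the implant volume is lost by 12 months, matching the
configured 0.45 expected fold.

An end-to-end orchestrated run (scenes → ROI → bands → phenotypes →
morphometry → mixed model, with CSV outputs and a provenance manifest):

```r
res <- run_pipeline(run_config(seed = 1), "run1")
res$slopes          # marginal distance slopes per group
```

A thin command-line wrapper lives at `inst/cli/implantquant.R`
(`run`, `simulate-scene`, `simulate-calipers`, `morphometry` subcommands).

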