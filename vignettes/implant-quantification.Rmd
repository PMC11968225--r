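---
title: "Spatial quantification of MAP implant sections: methods and design"
author: "implantquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial quantification of MAP implant sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantquant)
```

## The problem

Microporous annealed particle (MAP) scaffolds are injectable slurries of
~70 µm hydrogel microparticles that anneal in situ into a porous implant.
Assessing how the host responds to such an implant over months —
extracellular-matrix deposition, cell infiltration, vascularization,
immune-cell polarization, implant shrinkage — rests on a small set of
image-quantification procedures applied to immunofluorescence sections,
plus caliper morphometry and a spatial regression. This package
implements those procedures as tested, reusable code, and pairs them with
a synthetic-scene generator so that every stage can be validated against
known ground truth even though raw study images are not available.

The quantification stages are:

1. **ROI derivation** — isolate the implant cross-section from the DAPI
   channel (smooth, threshold, close, fill, keep the largest component).
2. **Concentric depth bands** — partition the ROI into fixed-width shells
   measured inward from the implant edge (100 µm by default) and report
   the fraction of positive pixels per band for each stain.
3. **Core/outer split** — erode the ROI to the cutoff depth at which the
   core holds 50% of the total area; count objects (e.g. CD31⁺ vessels,
   CD31⁺Podo⁺ lymphatics) per region, normalized to area.
4. **Spot phenotyping** — detect nuclear-scale spots per channel,
   deduplicate at 8 µm, and classify cells through distance rules
   (< 8 µm to a CD68 spot → macrophage; further < 8 µm to iNOS/Arg1 →
   M1/M2; CD3e/CD4 for T cells; within 2 µm of a TE-7 surface →
   fibroblast; Ki67 overlap → proliferating).
5. **Morphometry** — caliper length/width/height to volumes and
   per-implant fold changes relative to implantation.
6. **Distance-trend model** — a linear mixed model of band fraction
   against depth with group × timepoint × distance fixed effects and
   random intercepts for mouse and replicate image, summarized as
   marginal distance slopes with pairwise contrasts.

## Geometry: erosion as distance-transform thresholding

Band maps and the core/outer split are both defined through the
depth-from-edge map: the Euclidean distance from each interior pixel to
the ROI boundary, computed with a Euclidean distance transform rather
than by repeated morphological erosion with a pixel structuring element.
The two agree in the continuum limit, but the distance transform is
isotropic and exact in physical units, so a "band" is a true 100 µm
shell regardless of pixel size or boundary orientation. We subtract half
a pixel from the distance-to-background so that depth refers to the
continuum boundary of the mask rather than to background pixel centres,
and we pad the mask with a one-pixel background ring so that an ROI
touching the image frame is still bounded. Band `k` covers depths in
`[(k−1)Δ, kΔ)` (half-open), so bands tile the ROI exactly: band areas
always sum to the ROI area in pixels, and area-weighted band fractions
reconstruct the whole-ROI fraction identically. This conservation is
asserted in the tests rather than assumed.

The core/outer cutoff is located by bisection on the depth map and then
snapped to the nearest achievable discrete depth level; the achieved
inner-area fraction is reported and must lie within a tolerance (1
percentage point by default) of the target. On masks whose depth levels
are too coarse to achieve the target (a one-pixel-wide line is the
degenerate extreme) the function refuses and reports the best achievable
fraction rather than silently returning a bad split. For a disk of
radius R the cutoff for inner fraction f has the closed form R(1 − √f),
which the tests check to within one pixel.

## Thresholding

Thresholds are always computed over ROI pixels only, so slide background
cannot bias them, and the method and value are recorded in the returned
mask for provenance. Otsu is the default for general stains. Surface
stains used in the 2 µm proximity rule (TE-7) default to the triangle
method instead: a surface channel is a dominant unimodal background with
a sparse signal tail, and in that regime Otsu tends to split the
background mode and flood the mask, whereas the triangle construction
places the threshold at the foot of the background peak. Both methods,
plus fixed thresholds, are available everywhere; per-stain methods are a
configuration map.

## Spot phenotyping

The spot detector is deliberately simple and fully specified: Gaussian
smoothing at the nuclear scale (σ = 3 µm default), strict local maxima
of the smoothed response (plateau ties broken in raster order so results
are deterministic), a prominence floor relative to the image median, and
subpixel refinement by quadratic interpolation. Deduplication is greedy
in decreasing intensity with ties broken lexicographically by position —
chosen over unstated vendor heuristics because it is deterministic and
provable: every output pair is at least the minimum separation apart,
and the output is independent of input order. Distance rules follow the
stated inequalities literally: spot-to-spot rules are strict (“< 8 µm”),
the surface rule is inclusive (“within 2 µm”), with the surface distance
measured to the region boundary (nearest positive-pixel centre minus
half a pixel, zero inside). The Ki67 “effectively overlapping” rule has
no published distance; we use an inclusive 4 µm centre distance as a
configurable default. M1/M2 are non-exclusive flags gated on the
macrophage call, so a CD68⁺iNOS⁺Arg1⁺ cell counts in both; subclass
counts can therefore never exceed their parent, which is asserted across
random scenes. All nearest-neighbour logic is checked against all-pairs
brute-force oracles in the tests.

## Morphometry

Caliper dimensions convert to volume with the ellipsoid formula
V = π/6·l·w·h by default; a box formula is provided. Because all
downstream quantities are fold changes — ratios to the implantation
measurement — the formula constant cancels, and the tests assert the
exact factorization of the volume fold into dimension folds.
Regression-based outlier removal used by commercial software is not
reproduced; an optional, off-by-default median-absolute-deviation
flagger reports (never drops) suspect fold changes.

## The distance-trend mixed model

Band fractions are modeled on the identity scale (an optional logit mode
exists) as

```
fraction ~ group * timepoint * distance + (1 | mouse) + (1 | image)
```

with timepoint coded as a factor, distance as the band mid-depth in µm,
and replicate images nested within mouse (nesting is assumed because the
replicate structure is per-mouse; a crossed coding is not meaningful
here). Random slopes are not included: the scientific quantity is the
per-cell marginal slope, and random intercepts capture the dominant
section-to-section level shifts. Fits use REML via `lmerTest` so that
confidence intervals and contrasts use Satterthwaite degrees of freedom;
when a variance component collapses to zero the fit warns with the
component values rather than failing, since the fixed-effect estimates
remain valid. Marginal slopes per group × timepoint come from the
fitted covariance (`emtrends`-style), and pairwise slope contrasts use
Tukey multiplicity adjustment by default. Simulation tests verify ~95%
CI coverage of true slopes, exact recovery on noiseless data, OLS
equivalence when random effects are dropped, and family-wise error
control under the null.

## The synthetic-scene generator

The generator emulates the structure of the study's data, not its
optics. A scene is: an ROI (disk, ellipse, or smooth random blob,
~1 mm); a scaffold of hard-disk microparticles packed by random
sequential addition with diameters from a truncated normal (heparin
formulation 69.7 ± 2.25 µm, plain 68.8 ± 1.87 µm — the published spread
is treated as a population SD, and sentence order implies the heparin
formulation is the 69.7 µm one; both are swappable in configuration)
and exactly `round(N × 0.10)` particles flagged as heparin µislands (the
1:10 mixing ratio); cells placed by an inhomogeneous Poisson process
whose intensity is linear in depth from the edge; phenotype labels drawn
from configured class fractions with conditional marker probabilities;
and channels rendered as background plus a diffuse in-tissue elevation
inside the ROI, nuclear-scale Gaussian blobs (σ = 3 µm) per cell, marker
blobs jittered ~1 µm from the nucleus, and additive Gaussian noise.
The in-tissue elevation mirrors the real property that makes DAPI-based
cropping possible on slides — tissue is visibly brighter than bare
slide — and without it ROI derivation from sparse nuclei alone would be
ill-posed.

Default study conditions: 2 µm pixels; a 500 µm disk ROI; cell density
500 cells/mm² at the edge falling by 0.3 cells/mm² per µm of depth;
class fractions 30% macrophage, 10% T cell, 20% fibroblast, 10%
endothelial, remainder unlabeled; signal 100, background 10, tissue
elevation 15, noise SD 5 (5% of signal). The density is chosen for the
regime spot-based counting is valid in: at ~400–500 cells/mm² the large
majority of nearest-neighbour spacings exceed the ~8.5 µm scale at which
two nuclear blobs merge under a 3 µm detector, so ≥95% of cells are
individually resolvable. This matches how the study itself used spots
only for the sparser phenotyping markers and fell back to
percent-positive pixels for densely packed DAPI. Caliper series default
to the observed trajectory — a slight volume increase at 1 month, then
decline to a 0.45 volume fold (≈55% decrease) at 12 months — with
multiplicative lognormal noise of unit mean on each dimension so
configured folds are unbiased.

What the generator does **not** emulate: optics (no PSF, no chromatic
shift), particle fluorescence, autofluorescence texture, staining
artifacts, section folds, or 3D structure. Passing the recovery tests
therefore shows the pipeline is correct for well-registered,
shot-noise-limited sections with resolvable nuclei; it does not certify
performance on heavily degraded slides.

## Determinism and numerical choices

Every generator consumes a single integer seed; per-stage substreams are
derived by fixed offsets so stages are independently reproducible, and
the caller's RNG state is always restored. Generated output is
bit-reproducible given a configuration. Mixed-model fits are
deterministic (no stochastic optimization). Pixel indexing is 1-based
with pixel `i` centred at `(i − 0.5) × pixel_size`; all physical
quantities are carried in µm; anisotropic pixels are rejected.
Truncated-normal diameters are drawn by resampling non-positive values.
Connected components use 8-connectivity (the common particle-analysis
default), with the labeling checked against a flood-fill oracle.

## Problem sizes in the test suite

Tests run the generator at modest sizes chosen for quick iteration:
scenes of 220–560 px at 2 µm/px, 500-particle sizing experiments at
1 µm/px, 200-trial oracle sweeps with up to 500 spots, 200 simulated
mixed-model datasets (2 groups × 2 timepoints, 6 mice per group, 3
replicate images, 10 bands) for the coverage check, and 500 null
simulations at a smaller design for family-wise error. These sizes give
simulation standard errors comfortably inside the asserted tolerances.

## Known limitations

- Object counts assign straddling objects to a region by centroid; no
  fractional assignment.
- The spot detector has a single scale; strongly size-heterogeneous
  nuclei would need a multi-scale detector.
- Fractions are modeled on the identity scale by default; band fractions
  near 0 or 1 would be better served by the logit option.
- CD68⁺ fibroblast cross-reactivity is not corrected for; no published
  procedure exists.
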