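Package: implantquant
Title: Spatial Quantification of Microporous Annealed Particle Implant Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image quantification and morphometry for long-term hydrogel
    microparticle (MAP) scaffold implants. Derives implant regions of interest
    from DAPI staining, partitions them into fixed-width concentric depth bands
    and a 50%-area core/outer split, quantifies fraction-positive staining per
    band, counts and colocalizes thresholded objects, phenotypes cells by
    spot detection with distance-based marker rules, computes caliper-based
    volume fold changes, and fits linear mixed models of stain gradients
    versus depth with marginal slope contrasts. A synthetic-scene generator
    with known ground truth (particle scaffolds, radial cell gradients,
    marker colocalization, caliper series) makes every stage verifiable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    lmerTest,
    emmeans,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
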