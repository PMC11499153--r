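Package: ECSmorph
Title: Extracellular-Space Diffusion Parameters and Astrocyte Volume
    Morphometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for two complementary assays of cell-volume
    dynamics in nervous tissue. The first is the real-time iontophoresis
    (RTI) method: tetramethylammonium (TMA+) is released from a
    current-driven point source and its concentration transient, recorded
    by an ion-selective microelectrode (ISM), is fitted with the modified
    diffusion equation to estimate the extracellular-space volume fraction
    (alpha), tortuosity (lambda) and non-specific uptake rate (k'). The
    package implements the closed-form forward model with overflow-safe
    erfcx evaluation, Nicolsky-Eisenman ISM calibration, agar calibration
    of the electrode transport number and free diffusion coefficient, and
    Nelder-Mead inverse fitting, cross-checked against an independent
    radial finite-difference solver. The second assay is 3D confocal
    morphometry: fluorescent-astrocyte z-stack time series are reduced by
    average-intensity projection, registered, photobleach-corrected,
    segmented by the Isodata intermeans threshold, and converted into
    normalized soma-volume time courses via the isotropic-scaling law
    Vs proportional to Ss^(3/2). Seeded synthetic generators produce
    diffusion traces, calibration series and astrocyte image phantoms with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    pracma,
    deSolve,
    minpack.lm,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Neuroscience, Visualization
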