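Package: gncadc
Title: Gradient Nonlinearity Bias Modelling and Correction for Trace Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spatial bias that gradient-coil nonlinearity (GNL) imposes on
    the diffusion weighting (b-value) of trace diffusion-weighted MRI, and applies the
    corresponding on-scanner-style correction (GNC) to apparent diffusion coefficient
    (ADC) maps. Provides a solid-harmonic gradient-coil field model with analytic
    Jacobians, per-voxel b-maps and percent bias maps, two-point trace ADC fitting,
    voxelwise GNC, MetaImage (MHD) volume input/output, a synthetic digital reference
    object phantom and a virtual bone-marrow cohort generator, region-of-interest
    histogram statistics, and test-retest Bland-Altman repeatability analysis for
    multi-site bone-marrow ADC studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
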