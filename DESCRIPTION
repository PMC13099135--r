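Package: layervein
Title: Velocity-Nulled Laminar fMRI: Vascular Attenuation Theory,
    Synthetic Draining-Vein Data, and Depth-Dependent Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for layer-resolved (laminar) functional MRI with
    velocity-nulling (VN) bipolar gradients. Implements the intravoxel
    incoherent motion (IVIM) pseudo-diffusion theory used to choose a VN
    b-value (per-compartment attenuation curves, bipolar b-value and
    critical-velocity calculators), a synthetic complex-valued laminar
    BOLD generator with an explicit draining-vein leakage operator and
    macrovascular phase, per-voxel phase regression, equidistant cortical
    layering with depth-dependent GLM activation profiles, and
    layer-specific functional connectivity (seed maps, intracortical
    depth-by-depth matrices, ROI-pair depth matrices) with Fisher-z
    group statistics under Benjamini-Hochberg FDR control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
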