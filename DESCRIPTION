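Package: pa4dflow
Title: Pulmonary Artery Hemodynamics from 4D Flow CMR Velocity Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing of time-resolved three-directional (4D flow)
    cardiovascular magnetic resonance velocity fields in the pulmonary
    arteries. Reads velocity volumes (NIfTI), time-resolved tetrahedral
    vessel meshes and branch centerlines (VTK XML), splits the vessel into
    main, left and right branch regions, extracts perpendicular
    cross-sections at fractional arc length, and computes geometric,
    velocity-profile and secondary-flow metrics: branch volume and area,
    relative area change, compliance and distensibility, flow rate and
    acceleration time ratio, centerline velocity, reverse-flow fraction,
    vorticity, helicity density, volume fraction of positive helicity,
    helical flow index, Dean number and Q-criterion vortex regions.
    Includes analytic flow phantoms (Poiseuille, solid-body, helical,
    Dean-pair, pulsating tube, Y-junction) with independent dense-quadrature
    ground truth for validation, and a longitudinal statistics stage with
    normality-gated paired comparisons and Spearman correlations on
    baseline values and pre/post deltas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
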