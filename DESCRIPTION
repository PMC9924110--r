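Package: protonWET
Title: Stopping-Power Ratio and Water-Equivalent Thickness Quality
    Assurance for Proton Immobilization Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying treatment-planning-system error in the
    stopping-power ratio (SPR) and water-equivalent thickness (WET) of
    proton-therapy immobilization devices, and for studying the dosimetric
    impact of such errors.  Provides an analytic pristine Bragg-peak model
    and a virtual multilayer ionization chamber for simulating integrated
    depth-dose curves; distal R80/R90 range extraction and WET/SPR
    estimation from range shifts; piecewise-linear HU-to-density and
    density-to-stopping-power calibration with exact (Siddon-style)
    radiological ray tracing through voxel phantoms; density override and
    a broad-beam spread-out-Bragg-peak dose engine with setup/range
    robustness scenarios; dose-volume-histogram metrics, worst-case
    robustness evaluation, beam-specific coverage metrics, and an exact
    Wilcoxon signed-rank test; plus CSV/NRRD input-output and a
    reproducible end-to-end study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
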