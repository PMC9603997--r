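Package: ponsPET
Title: Dynamic TSPO-PET Quantification for an Orthotopic Brainstem Glioma Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for dynamic brain PET studies of a
    diffuse intrinsic pontine glioma (DIPG) rat model imaged with the TSPO
    radioligand 18F-DPA-714. Provides SUV normalisation, volume-of-interest
    time-activity curve extraction, late-window static averaging,
    pons-to-striatum AUC ratios, image-derived whole-blood input functions,
    and Logan graphical analysis producing regional and voxel-wise total
    volume of distribution (V_T) estimates, together with a digital phantom
    generator that simulates complete dynamic studies and DIPG-versus-sham
    cohorts from reversible two-tissue-compartment kinetics with known
    ground truth. Includes the study-level statistical layer (two-group
    tests and structure-by-group ANOVA with Bonferroni adjustment) and a
    reproducible end-to-end workflow with manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
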