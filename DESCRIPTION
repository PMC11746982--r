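Package: spectable
Title: Patient-Table Effects in Attenuation-Corrected Myocardial SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic end-to-end pipeline for quantifying the effect of the
    patient table on CT-based attenuation correction in myocardial perfusion
    SPECT. Generates Jaszczak-type phantom and torso/left-ventricle CT and
    activity volumes with a parametric carbon-fibre patient table, removes the
    table from the CT by thresholding and morphological dilation, converts CT
    numbers to linear attenuation coefficients, simulates attenuated
    parallel-beam projections with energy-window scatter, reconstructs with
    ordered-subset expectation maximization (OSEM) with and without the table
    in the attenuation map, and compares the arms through percentage-difference
    volumes and AHA 17-segment polar-map perfusion scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
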