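Package: strokequant
Title: Quantitative Analysis of Preclinical Stroke Imaging and
    Extracellular-Vesicle Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transient middle cerebral artery
    occlusion (tMCAO) mouse studies: laser-speckle/multispectral
    hemodynamic time series (temporal downsampling, vessel masking,
    baseline-relative ischemic core/penumbra/normal segmentation,
    ischemic-core tracking, region trace extraction for flow and oxy-/
    deoxyhemoglobin), stereological infarct-volume estimation (2D
    nucleator, Cavalieri estimator), immunohistochemistry quantification
    (IgG/CD31 extravasation ratios, hemisphere-normalized homing
    fluorescence), behavioral endpoints (Hargreaves trimmed-mean latency,
    corner-test turn frequency, neurological scoring), and
    extracellular-vesicle sample bookkeeping (hemolysis QC, dose
    equalization, pooling, post/pre normalization). Includes synthetic
    phantom generators with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
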