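Package: colowave
Title: Microwave Colonoscopy Polyp Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection of colorectal polyps from sequences of single-frequency
    microwave transmission S-parameters acquired by a ring antenna array moving
    along the colon lumen. Implements automatic temporal subtraction calibration
    with frame matching by the modified Hausdorff distance, cross-sectional
    monofocusing image reconstruction with Bessel-function weighting, and an
    exponential-smoothing outlier detector that raises an alarm on frames whose
    image maximum exceeds its forecast confidence band. Includes a synthetic
    colon trajectory simulator (Born single-scattering forward model with wall
    clutter, fold drift, debris and noise) for generating test ensembles with
    ground-truth lesion extents, plus sensitivity/specificity evaluation and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
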