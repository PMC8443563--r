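Package: holotomo
Title: Label-Free Phase-Contrast Tomography of Rotating Plant-Cell Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pipeline for quantitative phase imaging of plant-cell nuclei that
    rotate during osmotic dehydration. Demodulates off-axis digital holograms,
    refocuses by angular-spectrum propagation with Tamura-coefficient
    autofocus, follows the dehydration dynamics (logistic global-contrast fit
    and plasmolysis detection), tracks nuclei in 3D, recovers the unknown
    rolling angles of a rigid triaxial-ellipsoid nucleus from the minor-axis
    lengths of its 2D projections, reconstructs a 3D refractive-index tomogram
    by filtered back-projection at non-uniform angles, and quantifies the
    nucleolus (segmentation, morphometry, refractive-index statistics, dry
    mass). Includes an analytic two-ellipsoid phantom generator so the whole
    chain is testable without experimental data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
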