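Package: gelqc
Title: Automated DNA Fragmentation Quality Control from Gel Electrophoresis Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Densitometric analysis of agarose gel electrophoresis images for
    DNA fragmentation quality control. Provides an automated pipeline that
    denoises a gel image, locates lane boundaries by vertical edge detection,
    calibrates pixel rows to base-pair sizes from a user-specified DNA ladder,
    and converts each sample lane into a base-pair-indexed intensity curve from
    which peak fragment sizes, relative peak areas and the percentage of signal
    within a target size range are computed. Includes a synthetic gel simulator
    with exact ground truth (lane boundaries, marker rows, analytic fragment
    size distributions) so every stage is testable without real gel images, and
    a batch command-line entry point that exports tidy CSV tables and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    jpeg,
    withr
Config/testthat/edition: 3
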