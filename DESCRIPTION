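Package: chromaquant
Title: Colorant Quantification from Digital Images of Cuvette Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies a colorant (e.g. the red azo food dye Allura Red AC,
    E129) from a single digital photograph of a cuvette array containing an
    analytical blank, calibration standards and unknown samples. Square
    regions of interest are converted to per-channel RGB histograms, means
    and blank-referenced reflectance signals; concentrations are estimated
    by univariate least-squares or PLS1 (NIPALS) multivariate calibration
    with leave-one-out latent-variable selection. Includes the standard
    analytical-validation toolkit (recovery, coefficient of variation,
    detection and quantification limits, regression diagnostics), per-sample
    two-method equivalence statistics (variance-ratio F, paired t, relative
    error, regulatory-limit compliance), a two-factor full-factorial design
    module with centre points for optimising acquisition conditions, and a
    synthetic scene generator with Beer-Lambert colour rendering for fully
    reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jpeg,
    jsonlite,
    lmtest,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
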