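Package: garf
Title: Genetic Algorithm-Random Forest QSAR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates quantitative structure-activity relationship
    (QSAR) regression models by coupling a binary genetic algorithm for
    descriptor selection with random-forest regression scored by out-of-bag
    mean squared error. Includes descriptor-matrix preprocessing (sparse-zero,
    near-zero-variance and pairwise-correlation filters), rational train/test
    splitting on a Kohonen self-organizing map, the Golbraikh-Tropsha and Roy
    external-validation battery (r2_pred, through-origin k and r2_o, r2_m),
    Y-randomization checks, and seeded synthetic data generators with known
    ground truth. Ships a transcription of a published 190-compound fructose
    1,6-bisphosphatase inhibitor benchmark for reproducible validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
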