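Package: innodiff
Title: Direct and Indirect Social Influence in the Diffusion of Innovations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the diffusion of innovations on social
    networks under both direct (nearest-neighbour) and indirect
    (distance-d) peer pressure. Implements d-path Laplacian consensus
    dynamics with a matrix-exponential solution, round discretization and
    threshold-based adopter curves; grid-search estimation of the indirect
    influence strengths (c_d), adoption threshold and time horizon from
    per-round adopter proportions; decay-law comparison experiments; a
    seeded generator of experiment-like session data (round-based colour
    choices with displayed peers, bots and stubborn agents); outlier and
    stubborn-participant detection; and decision-level random-forest
    feature importance with nested cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
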