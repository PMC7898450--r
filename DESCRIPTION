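Package: plnet
Title: Contextualization of Probabilistic Logic Signalling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative probabilistic-logic simulation of signed signalling
    networks and their contextualization against perturbation data from
    multiple cellular contexts (cell lines). Provides steady-state simulation
    of weighted logic models, joint multi-context parameter estimation by
    multi-start projected gradient descent with pruning (group partial-norm)
    and uniformity regularization, model selection on a regularization grid by
    the Bayesian Information Criterion, flux-based topology reduction with
    parameter merging, and parameter-uncertainty estimation by refitting on
    noise-resampled measurements. Includes a synthetic-data generator and a
    literature-style fixture network for the signalling pathways upstream of
    L-plastin Ser5 phosphorylation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
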