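Package: rivalnet
Title: Symmetry Analysis of Binocular Rivalry Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructs feature-typed rivalry networks for binocular rivalry
    experiments, computes their permutation symmetry groups and maximal fusion
    states, decomposes the node-permutation representation into isotypic
    components, classifies fusion-breaking Hopf bifurcations, enumerates the
    periodic solution branches and percept alternations predicted by
    equivariant Hopf theory, and verifies the predictions by simulating
    generalized Wilson firing-rate equations with per-coupling-class weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    deSolve,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
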