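Package: helimsm
Title: Markov State Model Analysis of Helicase Translocation on ssDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for the ATP-driven translocation mechanism of
    SF2-family 5'-3' DNA helicases (XPD and its bacterial homolog DinG) on
    single-stranded DNA. Provides seeded coarse-grained helicase-ssDNA
    ensemble generators with embedded Markovian kinetics, time-lagged
    independent component analysis (TICA), reversible Markov state model
    estimation with PCCA+ coarse-graining and mean first-passage time
    kinetics, nudged elastic band path optimization on analytic potentials,
    typed protein-DNA persistent contact analysis, constriction geometry and
    DNA register descriptors, and classification of disease mutations by
    their structural role in translocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
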