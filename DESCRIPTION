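Package: phenoburst
Title: Bursty Introduction of Novel Phenotypes on Genotype-Phenotype Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantifying non-Poissonian
    "bursts" in the mutational introduction of novel phenotypes on
    genotype-phenotype (GP) maps. Provides GP-map abstractions (RNA secondary
    structure via the ViennaRNA command-line tools, a hydrophobic-polar
    lattice protein model, Dawkins-style biomorphs, and seeded random maps),
    neutral-component extraction with robustness and mutation-spectrum
    statistics, a hierarchy of null models (random, topology and community
    maps), Wright-Fisher and average-rate population simulators with
    appearance logging, overdispersion statistics (interval counts,
    coefficient of variation, Poisson-mixture predictions), and closed-form
    origin-fixation theory for burst sizes, fixation times and multi-peak
    first-fixation probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    yaml
SystemRequirements: ViennaRNA (RNAsubopt on the PATH) for the RNA
    genotype-phenotype map; all other maps are self-contained.
Config/testthat/edition: 3
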