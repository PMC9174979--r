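Package: mitophylo
Title: Mitogenome Haplogroup Phylogeography and Molecular-Clock Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reference-relative haplotyping of whole mitogenomes and
    downstream phylogeographic analysis, built around the kind of survey used
    for barn swallow (Hirundo rustica) matrilines. Implements heteroplasmy-aware
    variant calling from per-site read fractions, mutation-annotated maximum
    parsimony trees with outgroup rooting and nested haplogroup nomenclature,
    molecular-clock node dating (rho statistic and strict-clock maximum
    likelihood under HKY+gamma), classic/generalized skyline demography,
    time-partitioned dN/dS under the vertebrate mitochondrial code with a Fisher
    exact test, population diversity and isolation-by-distance statistics, and a
    seeded coalescent simulator that generates every input the pipeline consumes
    together with ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    geosphere,
    vegan,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
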