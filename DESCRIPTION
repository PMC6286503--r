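Package: sitecb
Title: Compositional Bias and Avoidance of Restriction Sites in Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects avoidance of restriction-modification (R-M) recognition
    sites in the genomes of bacteriophages and other viruses. Computes the
    compositional bias (CB) of an IUPAC-degenerate site, the ratio of its
    observed count to an expectation derived by inclusion-exclusion over all
    subsites, classifies sites as eliminated or under-represented, builds
    experimental and control (site, genome) datasets from enzyme and host
    metadata, dereplicates genomes by k-mer identity, and summarises avoidance
    fractions across R-M system types, genome types and phage lifestyles with
    Fisher's exact comparisons. Includes a synthetic-genome generator with
    controlled per-site depletion so the whole pipeline runs without any
    sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
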