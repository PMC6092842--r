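Package: mtrecomb
Title: Repeat-Mediated Recombination in Plant Mitochondrial Genomes from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the repeat landscape of circular organellar
    genomes and for detecting repeat-mediated homologous recombination from
    accuracy-corrected long reads. Includes a built-in seed-and-extend local
    alignment engine with Karlin-Altschul e-values, repeat pair discovery and
    greedy incremental family clustering, construction of master and recombinant
    reference conformations per repeat pair, read classification with flanking
    coverage requirements and two-stage validation, per-pair recombination
    frequency estimation, plastid-derived insert detection, conserved gene
    cluster identification, double-cut-and-join rearrangement distance, and a
    synthetic-data module (circular genomes with planted repeats, alternative
    conformations at controlled stoichiometry, simulated error-bearing long
    reads) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
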