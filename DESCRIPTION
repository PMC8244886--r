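Package: hapnetdiv
Title: Haplotype Network Complexity Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the complexity of haplotype networks in
    population-genetic and phylogeographic studies. Collapses aligned DNA
    sequences into haplotypes, builds distance-based minimum spanning
    networks with equal-cost alternative links, decomposes haplotypes into
    degree-based classes, and computes haplotype diversity (Hd), node
    diversity (Nd), branch diversity (Bd), the combined complexity metrics
    HNd and HBd, and nucleotide diversity (pi). Includes a synthetic
    alignment generator that realizes prescribed network topologies for
    testing and benchmarking, tidy accessors for all results, and a
    command-line interface.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    tibble,
    tidyr,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
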