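Package: protoselect
Title: Ecology- and Phylogenomics-Driven Selection of Prototype Bacterial Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of an ecological and
    phylogenomic pipeline for choosing a prototype strain of a bacterial
    species (developed around Bifidobacterium longum subsp. longum). The
    pipeline covers genome quality control, fragment-based average nucleotide
    identity (ANI) and dereplication, k-mer based strain tracking across
    metagenome samples with prevalence estimation, the AxP prototype-ranking
    index (mean ANI x prevalence x 100), biobank candidate ranking by combined
    ANI and average percentage of positive-scoring matches (PPOS) from local
    protein alignments, pangenome gene-family clustering by Markov clustering
    with focal-strain unique-gene extraction, and a count-based differential
    expression stage (CPM filtering, TMM normalization, exact negative
    binomial test). A synthetic-data module generates genomes, metagenome
    read sets, proteomes and count matrices with known ground truth so that
    every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
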