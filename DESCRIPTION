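Package: poptree
Title: Population Phylogenies from Multi-Sample VCF Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streams multi-sample VCF files (plain text or gzipped), filters
    biallelic SNPs on site quality and per-sample read depth, accumulates
    pairwise genetic and drift distances between diploid genomes, and builds
    population phylogenies with UPGMA and classical neighbour-joining.
    Distance matrices can be rescaled to p-distances or Jukes-Cantor
    corrected distances given a genome length, and are exported in Newick,
    MEGA and PHYLIP formats. Includes a deterministic synthetic-VCF
    generator with exact expected pairwise counts for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
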