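Package: coremark
Title: Core-Genome Haplotype Marker Design and Amplicon Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a collinear core genome from multi-assembly
    whole-genome alignments, designing transferable haplotype amplicon markers
    inside it, and genotyping multiplexed amplicon sequencing reads into
    haplotype alleles. Includes k-mer frequency repeat masking, syntenic
    chaining of PAF alignments with one-to-one block selection, exponential
    convergence modelling of core-genome size, amplicon marker selection from
    panel variation, primer-based read demultiplexing with error collapsing,
    Mendelian segregation and hemizygosity (null-allele) tests, IBS/MDS
    quality control, and kinship-corrected mixed-model marker-trait
    association. A self-contained simulator generates pan-genomes, panel
    variants, biparental families and amplicon reads with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
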