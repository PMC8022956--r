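Package: crestmap
Title: Fine-Mapping of the Chicken Crest Locus from Synthetic Whole-Genome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the discovery pipeline for the chicken Crest
    mutation on a fully synthetic cohort: a seeded reference model of the
    chromosome 33 candidate region with the 197 bp tandem-duplication unit,
    builders for the five Crest-locus alleles (crWT, Cr1, Cr2, Cr3 and the
    single-copy back-mutant), identity-by-descent shared-haplotype scanning
    with phenotype-concordance filtering, tandem-duplication detection from
    split reads, everted pairs and read depth, Sanger-style allele
    classification (copy counting, copy-specific SNP reading and TG
    microsatellite typing), an in-silico PCR / KASP diagnostic assay with
    cohort genotype summaries, and delta-delta-Ct relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
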