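#!/usr/bin/env Rscript

# Build the synthetic reference model of the chromosome 33 candidate region
# and generate the whole-genome panel used by the downstream scans:
# 22 crested samples (18 individuals + 4 pools) and 197 non-crested
# individuals, with the duplication haplotype and its four linked SNVs
# planted at their true coordinates.

library(crestmap)

seed <- 1L
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

ref <- build_reference(seed)
print(ref)

cohort <- generate_cohort(ref, wgs_panel_design(), seed = seed)
print(cohort)
paths <- write_cohort(cohort, "results/cohort")

# reference and the five allele haplotypes as FASTA, for inspection
haps <- lapply(names(crest_alleles()), function(a)
  hap_sequence(ref, build_allele(ref, a)))
names(haps) <- names(crest_alleles())
seqs <- Biostrings::DNAStringSet(c(reference = ref$sequence,
                                   unlist(haps)))
Biostrings::writeXStringSet(seqs, "results/cohort/haplotypes.fasta")

message("sample sheet: ", paths$samples)
message("truth VCF:    ", paths$truth_vcf)
message("variants: ", nrow(cohort$matrix$variants),
        " | samples: ", nrow(cohort$samples))
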