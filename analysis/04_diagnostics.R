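#!/usr/bin/env Rscript

# Run the diagnostic assay (in-silico PCR with the Cr_197_F1/R1 primers,
# fragment interpretation, KASP SNP call, Sanger-style classification) on a
# cohort with the published per-breed composition, and summarise genotype
# counts per breed.

library(crestmap)

seed <- 1L
dir.create("results/diagnostics", showWarnings = FALSE, recursive = TRUE)

ref <- build_reference(seed)

# fragment sizes implied by the model
wt_len <- insilico_pcr(hap_sequence(ref, build_allele(ref, "crWT")))$length
dup_len <- insilico_pcr(hap_sequence(ref, build_allele(ref, "Cr1")))$length
message(sprintf("wild-type fragment %d bp, duplication fragment %d bp",
                wt_len, dup_len))

cohort <- generate_cohort(ref, table1_design(), seed = seed)
results <- diagnose_cohort(cohort, ref)
write.table(results, "results/diagnostics/diagnostics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- cohort_summary(results, cohort$samples)
write.table(tab, "results/diagnostics/cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab)
message(sprintf("diagnosed %d individuals; %d failed",
                nrow(results), sum(results$final_genotype == "fail")))

# the back-mutant route, exercised explicitly (two heterozygous carriers of
# the single-copy A haplotype, as found in non-crested Ameraucana)
wt <- hap_sequence(ref, build_allele(ref, "crWT"))
bm <- hap_sequence(ref, build_allele(ref, "Cr2_backmutant"))
amer <- diagnose_individual(wt, bm, ref, "Ameraucana_demo")
print(amer)
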