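#!/usr/bin/env Rscript

# Scan the 250 kb candidate region for the maximal interval shared
# (identical by descent) by all crested samples, then apply the
# phenotype-concordance filter to the variants inside it. On the default
# panel the top interval is chr33:7,585,881-7,587,784 (1.9 kb) and the
# filter leaves a single fully concordant variant: the 197 bp duplication.

library(crestmap)

seed <- 1L
dir.create("results/scan", showWarnings = FALSE, recursive = TRUE)

ref <- build_reference(seed)
cohort <- generate_cohort(ref, wgs_panel_design(), seed = seed)

intervals <- shared_interval_scan(cohort$matrix, crest_candidate_region(),
                                  mode = "homozygous_ibd")
write_ibd_bed(intervals, "chr33", "results/scan/ibd_intervals.bed")
print(head(intervals, 3))
message(sprintf("top shared interval: chr33:%d-%d (%.1f kb, %d sites)",
                intervals$start[1], intervals$end[1],
                intervals$length[1] / 1000,
                intervals$n_support_sites[1]))

top <- genomic_interval("chr33", intervals$start[1], intervals$end[1])
candidates <- concordance_filter(cohort$matrix, top)
write.table(candidates, "results/scan/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(candidates), " fully concordant candidate(s): ",
        paste(candidates$id, collapse = ", "))
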