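#!/usr/bin/env Rscript

# Relative-expression analysis in the style of the HOXC qPCR panels:
# delta-delta-Ct against a reference gene, scaled to the dorsal-skin
# calibrator. Raw Ct values are synthetic (the study's raw Cts are not
# published); the script demonstrates the normalisation behaviour on a
# cohort with a planted cranial-skin upregulation in crested birds.

library(crestmap)

seed <- 1L
set.seed(seed)
dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)

samples <- data.frame(
  sample_id = c("RJF_1", "RJF_2", "Silkie_1", "Silkie_2", "Polish_1",
                "Polish_2"),
  crested = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))

rows <- list()
for (i in seq_len(nrow(samples))) {
  for (tissue in c("dorsal", "cranial")) {
    # GAPDH reference around Ct 20; HOXC10 high in dorsal skin everywhere,
    # and ectopically high in cranial skin of crested birds only
    up <- tissue == "dorsal" || samples$crested[i]
    base_target <- if (up) 24 else 29
    for (gene in c("HOXC10", "GAPDH")) {
      mu <- if (gene == "GAPDH") 20 else base_target
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i], tissue = tissue, stage = "D1",
        gene = gene, ct = round(rnorm(3, mu, 0.15), 2), rep = 1:3)
    }
  }
}
ct <- do.call(rbind, rows)
write.table(ct, "results/expression/ct_values.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

folds <- relative_expression(ct, "HOXC10", "GAPDH",
                             calibrator = list(sample_id = "RJF_1",
                                               tissue = "dorsal"))
write.table(folds, "results/expression/fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(folds[order(folds$tissue, folds$sample_id), ])

cranial <- folds[folds$tissue == "cranial", ]
message(sprintf("median cranial fold, crested vs wild-type: %.2f vs %.2f",
                median(cranial$fold[cranial$sample_id %in%
                                      samples$sample_id[samples$crested]]),
                median(cranial$fold[cranial$sample_id %in%
                                      samples$sample_id[!samples$crested]])))
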