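#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged per (sample, tissue, stage, gene);
#' delta-Ct is the target Ct minus the reference-gene Ct; fold change is
#' `2^-(dCt - dCt_calibrator)`, so the calibrator sample's fold is exactly
#' 1. Amplification efficiency is fixed at 2. miRNA normalisation (e.g.
#' against let-7a) is the same computation with a different reference gene.
#'
#' @param ct Data.frame with columns `sample_id`, `tissue`, `stage`,
#'   `gene`, `ct`, `rep`.
#' @param target_gene,reference_gene Gene names present in `ct`.
#' @param calibrator List or vector with `sample_id` and `tissue` naming
#'   the calibrator (its first available stage is used).
#' @return Data.frame: `sample_id`, `tissue`, `stage`, `dct`, `fold`.
#'   Samples lacking the reference gene are omitted with a warning.
#' @export
relative_expression <- function(ct, target_gene, reference_gene,
                                calibrator) {
  stopifnot(all(c("sample_id", "tissue", "stage", "gene", "ct", "rep")
                %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  mean_ct <- stats::aggregate(ct ~ sample_id + tissue + stage + gene,
                              data = ct, FUN = mean)
  tg <- mean_ct[mean_ct$gene == target_gene, , drop = FALSE]
  rg <- mean_ct[mean_ct$gene == reference_gene, , drop = FALSE]
  m <- merge(tg, rg, by = c("sample_id", "tissue", "stage"),
             suffixes = c("_target", "_ref"))
  dropped <- setdiff(unique(tg$sample_id), unique(m$sample_id))
  if (length(dropped)) {
    warning("omitting sample(s) without reference gene: ",
            paste(dropped, collapse = ", "))
  }
  m$dct <- m$ct_target - m$ct_ref
  cal <- m$sample_id == calibrator$sample_id & m$tissue == calibrator$tissue
  if (!any(cal)) stop("calibrator not present for both genes")
  dct_cal <- m$dct[which(cal)[1]]
  data.frame(sample_id = m$sample_id, tissue = m$tissue, stage = m$stage,
             dct = m$dct, fold = 2^-(m$dct - dct_cal),
             stringsAsFactors = FALSE)
}
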