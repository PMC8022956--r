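#' @name vcf_io
#' @title VCF and sample-sheet I/O
#'
#' @description
#' The cohort's variants and genotypes travel as VCF 4.2 plus a TSV sample
#' sheet. Individuals carry diploid `GT` calls; pooled samples carry an
#' alt-allele frequency in a dedicated `AF` FORMAT field (`GT` is `./.` for
#' pools, `AF` is `.` for individuals). The tandem duplication is a symbolic
#' `<DUP>` ALT with `END`/`SVLEN` INFO. Parsing goes through vcfR; writing
#' emits the same subset.
NULL

PHENOTYPES <- c("crested_large", "crested_small", "crested_upward",
                "non_crested")

#' Read a sample sheet TSV
#'
#' Expected header: `sample_id breed phenotype sample_kind`.
#'
#' @param path TSV path.
#' @return Data.frame with validated columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "breed", "phenotype", "sample_kind")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  validate_sample_sheet(df[need])
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  bad <- setdiff(unique(df$phenotype), PHENOTYPES)
  if (length(bad)) stop("unknown phenotype(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$sample_kind), c("individual", "pool"))
  if (length(bad)) stop("unknown sample_kind(s): ",
                        paste(bad, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' @param variants Data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `vtype` (`SNV`, `INS` or `DUP`), `end` (NA except for `DUP`).
#' @param samples Sample-sheet data.frame.
#' @param geno Character matrix (variants x samples) of diploid genotypes
#'   (`0/0`, `0/1`, `1/1`, `./.`); NA in pool columns.
#' @param af Numeric matrix of pool alt-allele frequencies in `[0, 1]`;
#'   NA in individual columns.
#' @return Object of class `crest_genotypes`.
#' @export
genotype_matrix <- function(variants, samples, geno, af) {
  samples <- validate_sample_sheet(samples)
  o <- order(variants$pos)
  variants <- variants[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  af <- af[o, , drop = FALSE]
  rownames(variants) <- NULL
  stopifnot(nrow(geno) == nrow(variants), ncol(geno) == nrow(samples),
            identical(dim(geno), dim(af)))
  is_pool <- samples$sample_kind == "pool"
  if (any(!is.na(af[, !is_pool, drop = FALSE]))) {
    stop("AF entries are only allowed for pool samples")
  }
  bad <- variants$vtype == "SNV" &
    (nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)
  if (any(bad)) stop("SNV records must have 1 bp ref and alt")
  bad <- variants$vtype == "DUP" & !(variants$end > variants$pos)
  if (any(bad)) stop("DUP records must have end > pos")
  dimnames(geno) <- dimnames(af) <- list(variants$id, samples$sample_id)
  structure(list(variants = variants, samples = samples,
                 geno = geno, af = af),
            class = "crest_genotypes")
}

#' @export
print.crest_genotypes <- function(x, ...) {
  cat(sprintf("Crest genotype matrix: %d variant(s) x %d sample(s) (%d pool(s))\n",
              nrow(x$variants), nrow(x$samples),
              sum(x$samples$sample_kind == "pool")))
  invisible(x)
}

#' @export
dim.crest_genotypes <- function(x) c(nrow(x$variants), nrow(x$samples))

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm `crest_genotypes` object.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  is_pool <- gm$samples$sample_kind == "pool"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Pool alt allele frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t"))
  rows <- vapply(seq_len(nrow(v)), function(i) {
    info <- if (v$vtype[i] == "DUP") {
      sprintf("SVTYPE=DUP;END=%d;SVLEN=%d", v$end[i],
              v$end[i] - v$pos[i] + 1L)
    } else "."
    cells <- ifelse(is_pool,
                    paste0("./.:", formatC(gm$af[i, ], format = "g")),
                    paste0(gm$geno[i, ], ":."))
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            info, "GT:AF", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' @param path VCF path (the GT/AF subset written by [write_vcf()]).
#' @param sheet Sample-sheet data.frame matching the VCF sample columns.
#' @return `crest_genotypes` object with variants in ascending coordinate
#'   order. Errors name any VCF sample missing from the sheet and report
#'   the line number of a malformed genotype.
#' @export
read_vcf <- function(path, sheet) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  sample_ids <- colnames(gt_raw)[-1]
  missing <- setdiff(sample_ids, sheet$sample_id)
  if (length(missing)) {
    stop("sample(s) missing from the sample sheet: ",
         paste(missing, collapse = ", "))
  }
  sheet <- sheet[match(sample_ids, sheet$sample_id), , drop = FALSE]
  is_pool <- sheet$sample_kind == "pool"

  end <- suppressWarnings(as.integer(vapply(fix$INFO, function(x) {
    m <- regmatches(x, regexpr("(^|;)END=[0-9]+", x))
    if (length(m)) sub(".*END=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)))
  vtype <- ifelse(fix$ALT == "<DUP>", "DUP",
                  ifelse(nchar(fix$ALT) > nchar(fix$REF), "INS", "SNV"))
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT, vtype = vtype, end = end,
    stringsAsFactors = FALSE)

  gt_fields <- vcfR::extract.gt(vcf, element = "GT")
  af_fields <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE))
  geno <- matrix(NA_character_, nrow(variants), length(sample_ids))
  af <- matrix(NA_real_, nrow(variants), length(sample_ids))
  geno[, !is_pool] <- gt_fields[, !is_pool, drop = FALSE]
  geno[, !is_pool][is.na(geno[, !is_pool, drop = FALSE])] <- "./."
  af[, is_pool] <- af_fields[, is_pool, drop = FALSE]
  ok <- is.na(geno) | geno %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT '%s' at VCF body line %d (sample %s)",
                 geno[!ok][1], bad[1], sample_ids[bad[2]]))
  }
  genotype_matrix(variants, sheet, geno, af)
}
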