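#' @name sam_io
#' @title SAM alignment I/O
#'
#' @description
#' Reader and writer for the coordinate-sorted SAM subset the read simulator
#' emits: single reference sequence, paired-end reads, soft-clipped
#' primary/supplementary split alignments linked by `SA:Z` tags, M/I/S CIGAR
#' operations. Alignments are represented as a plain data.frame (class
#' `crest_alignments`) with the eleven mandatory SAM columns plus `sa`.
NULL

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

# reference bases consumed by an alignment
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_left_clip <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- cigar_ops(cg)
    if (nrow(ops) && ops$op[1] == "S") ops$len[1] else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Write alignments to a SAM file
#'
#' @param aln `crest_alignments` data.frame (see [simulate_alignments()]).
#' @param path Output path.
#' @param ref A `crest_reference` providing the `@SQ` header line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref) {
  aln <- aln[order(aln$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$region$chrom, ref$region$end))
  body <- do.call(paste, c(unname(as.list(aln[SAM_COLS])), sep = "\t"))
  has_sa <- !is.na(aln$sa) & nzchar(aln$sa)
  body[has_sa] <- paste0(body[has_sa], "\tSA:Z:", aln$sa[has_sa])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a coordinate-sorted SAM file
#'
#' @param path SAM file path.
#' @return `crest_alignments` data.frame with columns
#'   `r NULL` qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
#'   seq, qual, sa. Errors if the file is not coordinate-sorted.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) {
    out <- data.frame(
      qname = character(0), flag = integer(0), rname = character(0),
      pos = integer(0), mapq = integer(0), cigar = character(0),
      rnext = character(0), pnext = integer(0), tlen = integer(0),
      seq = character(0), qual = character(0), sa = character(0),
      stringsAsFactors = FALSE)
    class(out) <- c("crest_alignments", "data.frame")
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ",
         which(nf < 11L)[1] + sum(startsWith(lines, "@")))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(
    qname = col(1), flag = as.integer(col(2)), rname = col(3),
    pos = as.integer(col(4)), mapq = as.integer(col(5)), cigar = col(6),
    rnext = col(7), pnext = as.integer(col(8)), tlen = as.integer(col(9)),
    seq = col(10), qual = col(11), stringsAsFactors = FALSE)
  out$sa <- vapply(fields, function(f) {
    tag <- grep("^SA:Z:", f[-(1:11)], value = TRUE)
    if (length(tag)) sub("^SA:Z:", "", tag[1]) else NA_character_
  }, character(1))
  if (is.unsorted(out$pos)) stop("SAM input is not coordinate-sorted")
  class(out) <- c("crest_alignments", "data.frame")
  out
}

#' Assemble primary alignments into read pairs
#'
#' Groups primary records by query name into one row per sequenced fragment;
#' orphan mates are skipped with a warning.
#'
#' @param aln `crest_alignments` data.frame.
#' @return Data.frame with one row per pair: `qname`, and for each mate
#'   `pos`, `end`, `reverse` (strand), `cigar`.
#' @export
pair_alignments <- function(aln) {
  prim <- aln[bitwAnd(aln$flag, 2048L) == 0L, , drop = FALSE]
  first <- bitwAnd(prim$flag, 64L) > 0L
  m1 <- prim[first, , drop = FALSE]
  m2 <- prim[!first, , drop = FALSE]
  common <- intersect(m1$qname, m2$qname)
  orphans <- setdiff(union(m1$qname, m2$qname), common)
  if (length(orphans)) {
    warning(length(orphans), " orphan mate(s) skipped")
  }
  m1 <- m1[match(common, m1$qname), , drop = FALSE]
  m2 <- m2[match(common, m2$qname), , drop = FALSE]
  data.frame(
    qname = common,
    pos1 = m1$pos, end1 = m1$pos + cigar_ref_span(m1$cigar) - 1L,
    rev1 = bitwAnd(m1$flag, 16L) > 0L, cigar1 = m1$cigar,
    pos2 = m2$pos, end2 = m2$pos + cigar_ref_span(m2$cigar) - 1L,
    rev2 = bitwAnd(m2$flag, 16L) > 0L, cigar2 = m2$cigar,
    stringsAsFactors = FALSE)
}
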