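#' Count tandem copies of the duplication unit in a locus sequence
#'
#' Locates the unit between its two unique flanking anchor sequences and
#' decides whether one or two tandem copies are present, tolerating the
#' small copy-specific edits carried by the Crest alleles (up to
#' `max_edits` per copy, Levenshtein distance).
#'
#' @param seq Character scalar spanning the locus, containing both flanks.
#' @param unit_seq Reference sequence of the duplication unit.
#' @param flanks Character vector of length 2: the sequences immediately
#'   before and after the unit in the single-copy reference.
#' @param max_edits Maximum edits per copy before the sequence is rejected
#'   (default 3; the modelled allele edits are 1-2 bp).
#' @return List: `copy_count`, `copies` (character vector of copy
#'   sequences, 5' to 3'), `intervals` (start/end of each copy within
#'   `seq`).
#' @export
count_unit_copies <- function(seq, unit_seq, flanks, max_edits = 3L) {
  lf <- flanks[1]; rf <- flanks[2]
  li <- gregexpr(lf, seq, fixed = TRUE)[[1]]
  ri <- gregexpr(rf, seq, fixed = TRUE)[[1]]
  if (li[1] == -1L || ri[1] == -1L || length(li) != 1L || length(ri) != 1L) {
    stop("not the Crest locus: flanking anchors absent or not unique")
  }
  lo <- li[1] + attr(li, "match.length")[1]   # first base after left flank
  hi <- ri[1] - 1L                            # last base before right flank
  if (hi < lo) stop("not the Crest locus: flanks out of order")
  between <- substr(seq, lo, hi)
  ulen <- nchar(unit_seq)
  blen <- nchar(between)

  n_copies <- round(blen / ulen)
  if (!n_copies %in% c(1L, 2L) || abs(blen - n_copies * ulen) > max_edits) {
    return(list(copy_count = n_copies, copies = character(0),
                intervals = NULL))
  }
  if (n_copies == 1L) {
    if (utils::adist(between, unit_seq) > max_edits) {
      return(list(copy_count = 0L, copies = character(0), intervals = NULL))
    }
    return(list(copy_count = 1L, copies = between,
                intervals = data.frame(start = lo, end = hi)))
  }
  # two copies: choose the split minimising total edit distance; the 3'
  # copy keeps reference length in all modelled alleles, but nearby splits
  # are tried for robustness
  cands <- (blen - ulen) + (-max_edits:max_edits)
  cands <- cands[cands >= 1L & cands < blen]
  cost <- vapply(cands, function(s) {
    sum(utils::adist(substr(between, 1L, s), unit_seq),
        utils::adist(substr(between, s + 1L, blen), unit_seq))
  }, numeric(1))
  s <- cands[which.min(cost)]
  if (min(cost) > 2L * max_edits) {
    return(list(copy_count = 0L, copies = character(0), intervals = NULL))
  }
  list(copy_count = 2L,
       copies = c(substr(between, 1L, s), substr(between, s + 1L, blen)),
       intervals = data.frame(start = c(lo, lo + s),
                              end = c(lo + s - 1L, hi)))
}

#' Count TG repeat units at an anchored microsatellite
#'
#' Returns the length, in repeat units, of the maximal perfect TG run
#' containing the anchor position.
#'
#' @param copy_seq Sequence of one unit copy.
#' @param anchor_offset 1-based offset of the run anchor within the copy.
#' @return Integer repeat count; 0 when the anchor base is neither T nor G.
#' @export
count_tg_repeats <- function(copy_seq, anchor_offset) {
  if (anchor_offset < 1L || anchor_offset > nchar(copy_seq)) return(0L)
  if (!substr(copy_seq, anchor_offset, anchor_offset) %in% c("T", "G")) {
    return(0L)
  }
  m <- gregexpr("(TG)+", copy_seq)[[1]]
  if (m[1] == -1L) return(0L)
  len <- attr(m, "match.length")
  hit <- which(m <= anchor_offset & m + len - 1L >= anchor_offset)
  if (!length(hit)) return(0L)
  len[hit[1]] %/% 2L
}

#' Classify a Crest-locus sequence into one of the five alleles
#'
#' Implements the Sanger-interpretation decision table: copy counting,
#' reading the C/A base at unit offset 42 (g.7,587,629) in each copy, and
#' typing the TG run at unit offset 107 (g.7,587,694). One copy with C is
#' `crWT`; one copy with A is the `Cr2_backmutant` haplotype; two copies
#' with A in the 3' copy is `Cr2`; two copies with an expanded (TG)8 run in
#' the 5' copy is `Cr3`; two unedited copies is `Cr1`; anything else is
#' `unknown`.
#'
#' @param seq Locus sequence (e.g. from [hap_sequence()] or a Sanger
#'   amplicon spanning the unit with both flanks).
#' @param ref A `crest_reference` supplying the unit and flank anchors.
#' @param flank_width Anchor width in bp (default 30).
#' @param max_edits Per-copy edit tolerance (default 3).
#' @return List of class `allele_call`: `allele`, `copy_count`,
#'   `snp_bases` (per copy), `tg_counts` (per copy), `intervals`, `note`.
#' @export
classify_allele <- function(seq, ref, flank_width = 30L, max_edits = 3L) {
  co <- ref$coords
  unit_seq <- ref_slice(ref, co$unit_start, co$unit_end)
  flanks <- c(ref_slice(ref, co$unit_start - flank_width, co$unit_start - 1L),
              ref_slice(ref, co$unit_end + 1L, co$unit_end + flank_width))
  cp <- tryCatch(count_unit_copies(seq, unit_seq, flanks, max_edits),
                 error = function(e) {
                   list(copy_count = 0L, copies = character(0),
                        intervals = NULL, note = conditionMessage(e))
                 })
  snp_off <- co$snp_pos - co$unit_start + 1L    # 42
  tg_off <- co$tg_pos - co$unit_start + 1L      # 107

  if (cp$copy_count > 2L) {
    return(allele_call("unknown", cp,
                       note = sprintf("%d unit copies found", cp$copy_count)))
  }
  if (cp$copy_count < 1L || !length(cp$copies)) {
    return(allele_call("unknown", cp, note = "no recognisable unit copy"))
  }
  snp <- vapply(cp$copies, substr, character(1), snp_off, snp_off,
                USE.NAMES = FALSE)
  tg <- vapply(cp$copies, count_tg_repeats, integer(1), tg_off,
               USE.NAMES = FALSE)

  allele <- if (cp$copy_count == 1L) {
    if (snp == "C" && tg == 7L) "crWT"
    else if (snp == "A" && tg == 7L) "Cr2_backmutant"
    else "unknown"
  } else {
    if (snp[2] == "A" && snp[1] == "C" && all(tg == 7L)) "Cr2"
    else if (tg[1] == 8L && tg[2] == 7L && all(snp == "C")) "Cr3"
    else if (all(snp == "C") && all(tg == 7L)) "Cr1"
    else "unknown"
  }
  allele_call(allele, cp, snp_bases = snp, tg_counts = tg)
}

allele_call <- function(allele, cp, snp_bases = character(0),
                        tg_counts = integer(0), note = NA_character_) {
  structure(list(allele = allele, copy_count = cp$copy_count,
                 snp_bases = snp_bases, tg_counts = tg_counts,
                 intervals = cp$intervals, note = note),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("Crest allele call: %s (%d copies", x$allele, x$copy_count))
  if (length(x$snp_bases)) {
    cat(sprintf("; SNP %s; TG %s", paste(x$snp_bases, collapse = "/"),
                paste(x$tg_counts, collapse = "/")))
  }
  cat(")\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Diploid genotype label from two locus sequences
#'
#' @param seq_a,seq_b The two haplotype sequences of one individual.
#' @param ref A `crest_reference`.
#' @return Genotype string such as `"Cr2/Cr3"` (alleles in alphabetical
#'   order), or `"unknown"` when either haplotype fails to classify.
#' @export
classify_diploid <- function(seq_a, seq_b, ref) {
  a <- classify_allele(seq_a, ref)$allele
  b <- classify_allele(seq_b, ref)$allele
  genotype_label(a, b)
}

genotype_label <- function(a, b) {
  if (a == "unknown" || b == "unknown") return("unknown")
  paste(sort(c(a, b), method = "radix"), collapse = "/")
}
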