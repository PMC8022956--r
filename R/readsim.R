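#' Simulate paired-end alignments from a haplotype pair
#'
#' Draws sequencing fragments along each haplotype and places every read on
#' the reference analytically from the haplotype's block map — no aligner is
#' involved. Reads spanning the tandem-duplication junction are emitted as
#' split alignments (primary + supplementary, linked by `SA` tags) with
#' exact clip lengths; fragments straddling the junction produce the everted
#' (reverse-before-forward) pair orientation characteristic of a tandem
#' duplication. The 2 bp microsatellite expansion of Cr3 appears as an `I`
#' CIGAR operation.
#'
#' Coverage is the total diploid depth: each haplotype receives half.
#'
#' @param ref A `crest_reference`.
#' @param haps List of two `crest_haplotype` objects (the diploid genome).
#' @param coverage Mean diploid depth (default 20).
#' @param read_len Read length in bp (default 100).
#' @param frag_mean,frag_sd Fragment length distribution (default 350 +/- 50).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param region Optional [genomic_interval()] restricting simulation; its
#'   endpoints must lie outside the duplication unit. Default: whole model.
#' @param seed Integer seed; simulation is deterministic per seed.
#' @param min_anchor Minimum aligned length (bp) for a supplementary split
#'   segment to be reported (shorter remnants stay soft-clipped).
#' @return `crest_alignments` data.frame, coordinate-sorted.
#' @export
simulate_alignments <- function(ref, haps, coverage = 20, read_len = 100L,
                                frag_mean = 350, frag_sd = 50,
                                error_rate = 0, region = NULL, seed = 1L,
                                min_anchor = 15L) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (inherits(haps, "crest_haplotype")) haps <- list(haps, haps)
  stopifnot(length(haps) == 2L)
  if (is.null(region)) region <- ref$region
  recs <- list()
  for (k in 1:2) {
    recs[[k]] <- withr::with_seed(seed * 2L + k, {
      sim_hap_reads(ref, haps[[k]], coverage / 2, read_len, frag_mean,
                    frag_sd, error_rate, region, min_anchor,
                    prefix = sprintf("frag_h%d", k))
    })
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("crest_alignments", "data.frame")
  out
}

sim_hap_reads <- function(ref, hap, depth, read_len, frag_mean, frag_sd,
                          error_rate, region, min_anchor, prefix) {
  hs <- g2h(hap, region$start)
  he <- g2h(hap, region$end)
  if (!is.na(hap$blocks$rstart[nrow(hap$blocks)])) {
    # map region end through the last block covering it (unique outside unit)
    b <- hap$blocks
    i <- max(which(!is.na(b$rstart) & b$rstart <= region$end &
                     b$rstart + b$len > region$end))
    he <- b$hstart[i] + as.integer(region$end - b$rstart[i])
  }
  span <- he - hs + 1L
  n_frag <- max(1L, round(depth * span / (2 * read_len)))
  flen <- pmin(span, pmax(2L * read_len,
                          round(stats::rnorm(n_frag, frag_mean, frag_sd))))
  start <- hs + floor(stats::runif(n_frag) * (span - flen + 1))
  hseq <- hap_sequence(ref, hap)

  a1 <- start; b1 <- start + read_len - 1L
  a2 <- start + flen - read_len; b2 <- start + flen - 1L
  qname <- sprintf("%s_%06d", prefix, seq_len(n_frag))

  place <- function(a, b) place_reads(ref, hap, hseq, a, b, error_rate,
                                      min_anchor)
  p1 <- place(a1, b1)
  p2 <- place(a2, b2)

  # flags: read1 forward, read2 reverse; proper-pair bit when FR-oriented
  fr <- (p1$pos <= p2$pos)                    # forward mate leftmost?
  proper <- ifelse(fr, 2L, 0L)
  f1 <- 1L + proper + 32L + 64L
  f2 <- 1L + proper + 16L + 128L
  tl_lo <- pmin(p1$pos, p2$pos)
  tl_hi <- pmax(p1$end, p2$end)
  tlen1 <- ifelse(p1$pos <= p2$pos, tl_hi - tl_lo + 1L,
                  -(tl_hi - tl_lo + 1L))

  build <- function(p, flag, mate, tlen) {
    prim <- data.frame(
      qname = qname, flag = flag, rname = ref$region$chrom, pos = p$pos,
      mapq = 60L, cigar = p$cigar, rnext = "=", pnext = mate$pos,
      tlen = tlen, seq = p$seq, qual = strrep("I", read_len),
      sa = p$sa, stringsAsFactors = FALSE)
    if (length(p$extra)) {
      supp <- do.call(rbind, p$extra)
      supp$flag <- flag[supp$idx] + 2048L
      supp$qname <- qname[supp$idx]
      supp$rname <- ref$region$chrom
      supp$mapq <- 60L
      supp$rnext <- "="
      supp$pnext <- mate$pos[supp$idx]
      supp$tlen <- 0L
      supp$qual <- strrep("I", read_len)
      supp <- supp[names(prim)]
      rbind(prim, supp)
    } else prim
  }
  rbind(build(p1, f1, p2, tlen1), build(p2, f2, p1, -tlen1))
}

# Place reads [a, b] (haplotype coords) on the reference. Fast path for
# reads inside a single mapped block; block-walking otherwise.
place_reads <- function(ref, hap, hseq, a, b, error_rate, min_anchor) {
  blk <- hap$blocks
  n <- length(a)
  ia <- findInterval(a, blk$hstart)
  ib <- findInterval(b, blk$hstart)
  simple <- ia == ib & !is.na(blk$rstart[ia])
  pos <- integer(n); cigar <- character(n); endp <- integer(n)
  sa <- rep(NA_character_, n)
  pos[simple] <- as.integer(blk$rstart[ia[simple]] +
                              (a[simple] - blk$hstart[ia[simple]]))
  cigar[simple] <- paste0(b[simple] - a[simple] + 1L, "M")
  endp[simple] <- pos[simple] + (b[simple] - a[simple])
  extra <- list()
  for (i in which(!simple)) {
    segs <- segment_read(hap, a[i], b[i])
    segs <- segs[order(-segs$mlen), , drop = FALSE]
    keep <- segs$mlen >= min_anchor
    keep[1] <- TRUE                       # primary always reported
    segs <- segs[keep, , drop = FALSE]
    pos[i] <- segs$ref_start[1]
    cigar[i] <- segs$cigar[1]
    endp[i] <- segs$ref_start[1] + segs$ref_span[1] - 1L
    if (nrow(segs) > 1L) {
      sa_of <- function(j) paste0(
        ref$region$chrom, ",", segs$ref_start[j], ",+,", segs$cigar[j],
        ",60,0;")
      sa[i] <- paste(vapply(2:nrow(segs), sa_of, character(1)),
                     collapse = "")
      for (j in 2:nrow(segs)) {
        extra[[length(extra) + 1L]] <- data.frame(
          idx = i, pos = segs$ref_start[j], cigar = segs$cigar[j],
          seq = substr(hseq, a[i], b[i]), sa = sa_of(1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  seqs <- substring(hseq, a, b)
  if (error_rate > 0) seqs <- add_seq_errors(seqs, error_rate)
  list(pos = pos, end = endp, cigar = cigar, seq = seqs, sa = sa,
       extra = extra)
}

# Decompose a haplotype interval into reference-collinear segments.
segment_read <- function(hap, a, b) {
  blk <- hap$blocks
  hit <- which(blk$hstart <= b & blk$hstart + blk$len - 1L >= a)
  segs <- list()
  cur <- NULL
  pend_ins <- 0L
  for (i in hit) {
    ps <- max(a, blk$hstart[i])
    pe <- min(b, blk$hstart[i] + blk$len[i] - 1L)
    plen <- pe - ps + 1L
    if (is.na(blk$rstart[i])) {
      pend_ins <- pend_ins + plen
      next
    }
    rs <- as.integer(blk$rstart[i] + (ps - blk$hstart[i]))
    if (!is.null(cur) && rs == cur$ref_end + 1L) {
      if (pend_ins > 0L) cur$ops <- c(cur$ops, sprintf("%dI", pend_ins))
      cur$ops <- c(cur$ops, sprintf("%dM", plen))
      cur$ref_end <- rs + plen - 1L
      cur$used <- cur$used + pend_ins + plen
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
      cur <- list(ref_start = rs, ref_end = rs + plen - 1L,
                  ops = sprintf("%dM", plen), read_off = (ps - a),
                  used = plen)
    }
    pend_ins <- 0L
  }
  if (!is.null(cur)) segs[[length(segs) + 1L]] <- cur
  rl <- b - a + 1L
  do.call(rbind, lapply(segs, function(sg) {
    lcl <- sg$read_off
    rcl <- rl - lcl - sg$used
    cg <- paste0(if (lcl > 0L) paste0(lcl, "S") else "",
                 paste(sg$ops, collapse = ""),
                 if (rcl > 0L) paste0(rcl, "S") else "")
    mlen <- sum(as.integer(sub("M", "", grep("M$", sg$ops, value = TRUE))))
    data.frame(ref_start = sg$ref_start,
               ref_span = sg$ref_end - sg$ref_start + 1L,
               cigar = cg, mlen = mlen, stringsAsFactors = FALSE)
  }))
}

add_seq_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < rate)
    for (i in hits) {
      cur <- substr(s, i, i)
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}
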