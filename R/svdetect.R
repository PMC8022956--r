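#' Collect tandem-duplication evidence from alignments
#'
#' Extracts the three read-level signatures of a tandem duplication from a
#' region: everted read-pair clusters (mates oriented away from each other,
#' reverse mate leftmost), split-read junctions (the join from the end of
#' one unit copy to the start of the next, with exact clip positions), and
#' the per-base depth profile.
#'
#' @param aln `crest_alignments` data.frame (e.g. from [read_sam()] or
#'   [simulate_alignments()]).
#' @param region [genomic_interval()] to inspect.
#' @param cluster_gap Maximum distance (bp) between members of an everted
#'   cluster (default 500).
#' @param min_cluster Minimum everted pairs per reported cluster (default 2).
#' @return List of class `dup_evidence`: `junctions` (data.frame
#'   `donor_end`, `acceptor_start`, `support`), `everted` (data.frame
#'   `lo`, `hi`, `support`), `depth` (integer vector), `depth_start`
#'   (genomic position of `depth[1]`), `region`.
#' @export
collect_evidence <- function(aln, region, cluster_gap = 500L,
                             min_cluster = 2L) {
  prim <- aln[bitwAnd(aln$flag, 2048L) == 0L, , drop = FALSE]
  in_region <- function(p) p >= region$start & p <= region$end

  # --- split-read junctions ---
  sp <- prim[!is.na(prim$sa) & nzchar(prim$sa), , drop = FALSE]
  junc <- data.frame(donor_end = integer(0), acceptor_start = integer(0))
  if (nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      sa1 <- strsplit(sp$sa[i], ";", fixed = TRUE)[[1]][1]
      f <- strsplit(sa1, ",", fixed = TRUE)[[1]]
      sa_pos <- as.integer(f[2]); sa_cigar <- f[4]
      # the read part with the smaller left clip comes first on the read
      lc_p <- cigar_left_clip(sp$cigar[i])
      lc_s <- cigar_left_clip(sa_cigar)
      if (lc_p <= lc_s) {
        donor <- sp$pos[i] + cigar_ref_span(sp$cigar[i]) - 1L
        acceptor <- sa_pos
      } else {
        donor <- sa_pos + cigar_ref_span(sa_cigar) - 1L
        acceptor <- sp$pos[i]
      }
      if (acceptor < donor && in_region(donor) && in_region(acceptor)) {
        junc[nrow(junc) + 1L, ] <- c(donor, acceptor)
      }
    }
  }
  if (nrow(junc)) {
    tab <- stats::aggregate(list(support = junc$donor_end),
                            by = junc[c("donor_end", "acceptor_start")],
                            FUN = length)
    tab <- tab[order(-tab$support), , drop = FALSE]
  } else {
    tab <- data.frame(donor_end = integer(0), acceptor_start = integer(0),
                      support = integer(0))
  }

  # --- everted pairs (RF orientation: leftmost mate reverse) ---
  pairs <- suppressWarnings(pair_alignments(aln))
  lo_rev <- ifelse(pairs$pos1 <= pairs$pos2, pairs$rev1, pairs$rev2)
  hi_rev <- ifelse(pairs$pos1 <= pairs$pos2, pairs$rev2, pairs$rev1)
  ev <- pairs[lo_rev & !hi_rev, , drop = FALSE]
  everted <- data.frame(lo = integer(0), hi = integer(0),
                        support = integer(0))
  if (nrow(ev)) {
    lo <- pmin(ev$pos1, ev$pos2)
    hi <- pmax(ev$end1, ev$end2)
    keep <- in_region(lo) & in_region(hi)
    lo <- lo[keep]; hi <- hi[keep]
    if (length(lo)) {
      o <- order(lo)
      lo <- lo[o]; hi <- hi[o]
      grp <- cumsum(c(1L, diff(lo) > cluster_gap))
      everted <- do.call(rbind, lapply(split(seq_along(lo), grp), function(ix) {
        data.frame(lo = min(lo[ix]), hi = max(hi[ix]),
                   support = length(ix))
      }))
      everted <- everted[everted$support >= min_cluster, , drop = FALSE]
      rownames(everted) <- NULL
    }
  }

  # --- depth profile over the region (aligned M bases, splits included) ---
  spans <- IRanges::IRanges(start = aln$pos,
                            width = cigar_ref_span(aln$cigar))
  cov <- IRanges::coverage(spans, width = region$end)
  depth <- as.integer(S4Vectors::window(cov, region$start, region$end))

  structure(list(junctions = tab, everted = everted, depth = depth,
                 depth_start = region$start, region = region),
            class = "dup_evidence")
}

#' Depth ratio of a candidate duplication unit over its flanks
#'
#' @param depth Integer depth vector.
#' @param depth_start Genomic position of `depth[1]`.
#' @param unit [genomic_interval()] of the candidate unit.
#' @param flank Flank width in bp on each side (default 2000).
#' @return Mean depth inside the unit divided by mean flank depth.
#' @export
depth_ratio <- function(depth, depth_start, unit, flank = 2000L) {
  i <- function(g) g - depth_start + 1L
  n <- length(depth)
  inside <- depth[max(1L, i(unit$start)):min(n, i(unit$end))]
  fl <- c(depth[max(1L, i(unit$start - flank)):max(1L, i(unit$start - 1L))],
          depth[min(n, i(unit$end + 1L)):min(n, i(unit$end + flank))])
  if (mean(fl) == 0) stop("zero flank depth; cannot form depth ratio")
  mean(inside) / mean(fl)
}

# Left-align a junction through any microhomology (VCF convention):
# while the base at the donor end equals the base just before the acceptor,
# both breakpoints shift one base left.
left_align_junction <- function(ref, donor_end, acceptor_start) {
  base <- function(g) substr(ref$sequence, g2i(ref, g), g2i(ref, g))
  while (acceptor_start > ref$region$start &&
         base(donor_end) == base(acceptor_start - 1L)) {
    donor_end <- donor_end - 1L
    acceptor_start <- acceptor_start - 1L
  }
  c(donor_end = donor_end, acceptor_start = acceptor_start)
}

#' Call tandem duplications from collected evidence
#'
#' Breakpoints are taken from the modal split-read junction, left-aligned
#' through any microhomology against the reference. The genotype comes from
#' the depth ratio over the called unit (heterozygous for ratios in
#' `[het_lo, hom_lo)`, homozygous at or above `hom_lo`); when the ratio
#' falls below `het_lo` the junction-read fraction breaks the tie.
#'
#' @param evidence A `dup_evidence` object from [collect_evidence()].
#' @param ref A `crest_reference` (for microhomology left-alignment).
#' @param min_support Minimum combined split-read + everted-pair support
#'   (default 3).
#' @param het_lo,hom_lo Depth-ratio genotype boundaries (defaults 1.25 and
#'   1.75).
#' @param flank Flank width for the depth ratio (default 2000 bp).
#' @return Data.frame of class `dup_calls`: `start`, `end`, `unit_length`,
#'   `genotype`, `pe_support`, `sr_support`, `depth_ratio`, `flagged`
#'   (TRUE when overlapping junction clusters conflict). Zero rows when no
#'   duplication is supported.
#' @export
call_tandem_dup <- function(evidence, ref, min_support = 3L,
                            het_lo = 1.25, hom_lo = 1.75, flank = 2000L) {
  out <- data.frame(start = integer(0), end = integer(0),
                    unit_length = integer(0), genotype = character(0),
                    pe_support = integer(0), sr_support = integer(0),
                    depth_ratio = numeric(0), flagged = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("dup_calls", "data.frame")
  jn <- evidence$junctions
  if (!nrow(jn)) return(out)

  # left-align each junction cluster, then merge clusters that collapse
  aligned <- t(vapply(seq_len(nrow(jn)), function(i) {
    left_align_junction(ref, jn$donor_end[i], jn$acceptor_start[i])
  }, c(donor_end = 0L, acceptor_start = 0L)))
  jn$donor_end <- aligned[, "donor_end"]
  jn$acceptor_start <- aligned[, "acceptor_start"]
  jn <- stats::aggregate(list(support = jn$support),
                         by = jn[c("donor_end", "acceptor_start")], FUN = sum)
  jn <- jn[order(-jn$support), , drop = FALSE]

  for (i in seq_len(nrow(jn))) {
    start <- jn$acceptor_start[i]
    end <- jn$donor_end[i]
    pe <- 0L
    if (nrow(evidence$everted)) {
      hit <- evidence$everted$lo <= end & evidence$everted$hi >= start
      pe <- sum(evidence$everted$support[hit])
    }
    sr <- jn$support[i]
    if (pe + sr < min_support) next
    unit <- genomic_interval(evidence$region$chrom, start, end)
    dr <- depth_ratio(evidence$depth, evidence$depth_start, unit, flank)
    gt <- if (dr >= hom_lo) "hom" else if (dr >= het_lo) "het" else {
      # tiebreak on the fraction of junction-spanning reads at the acceptor
      jf <- sr / max(1L, evidence$depth[start - evidence$depth_start + 1L])
      if (jf > 0.7) "hom" else "het"
    }
    out[nrow(out) + 1L, ] <- list(start, end, end - start + 1L, gt,
                                  pe, sr, dr, FALSE)
  }
  if (nrow(out) > 1L) {
    # flag overlapping conflicting calls
    for (i in seq_len(nrow(out))) {
      ov <- out$start <= out$end[i] & out$end >= out$start[i]
      out$flagged[i] <- sum(ov) > 1L
    }
  }
  out <- out[order(-(out$pe_support + out$sr_support)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dup_calls", "data.frame")
  out
}
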