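#' Phenotype concordance of a single variant site
#'
#' Tests whether one variant site is compatible with all crested samples
#' having inherited the locus from a common ancestor. In the default
#' `homozygous_ibd` mode the site is concordant when a single allele exists
#' for which every case individual is homozygous and every case pool is
#' (near-)fixed; `dominant_carrier` only requires every case to carry at
#' least one copy.
#'
#' @param geno Character vector of diploid genotypes (`0/0`, `0/1`, `1/1`,
#'   `./.`); NA entries for pools.
#' @param af Numeric vector of pool alt frequencies; NA for individuals.
#' @param is_case Logical vector marking crested samples.
#' @param is_pool Logical vector marking pools.
#' @param mode `"homozygous_ibd"` (default) or `"dominant_carrier"`.
#' @param pool_fix_threshold Pool frequency at or above which a pool counts
#'   as fixed for the alt allele (and `1 - threshold` below which it counts
#'   as fixed reference). Default 0.95.
#' @param missing_policy `"strict"` (default): a missing case genotype
#'   breaks concordance; `"permissive"`: missing genotypes are compatible.
#' @return List with `concordant` (logical) and `shared_allele`
#'   (`"ref"`, `"alt"` or NA).
#' @export
site_concordance <- function(geno, af, is_case, is_pool,
                             mode = c("homozygous_ibd", "dominant_carrier"),
                             pool_fix_threshold = 0.95,
                             missing_policy = c("strict", "permissive")) {
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  if (!any(is_case)) stop("no case samples")
  dose <- gt_dose(geno)
  ci <- is_case & !is_pool
  cp <- is_case & is_pool
  d <- dose[ci]
  miss <- is.na(d)
  if (missing_policy == "strict" && any(miss)) {
    return(list(concordant = FALSE, shared_allele = NA_character_))
  }
  d <- d[!miss]
  p <- af[cp]

  ok_for <- function(allele) {
    if (mode == "homozygous_ibd") {
      ind_ok <- all(d == if (allele == "alt") 2L else 0L)
      pool_ok <- all(if (allele == "alt") p >= pool_fix_threshold
                     else p <= 1 - pool_fix_threshold)
    } else {
      ind_ok <- if (allele == "alt") all(d >= 1L) else all(d <= 1L)
      pool_ok <- all(if (allele == "alt") p > 1 - pool_fix_threshold
                     else p < pool_fix_threshold)
    }
    ind_ok && pool_ok
  }
  for (allele in c("alt", "ref")) {
    if (ok_for(allele)) {
      return(list(concordant = TRUE, shared_allele = allele))
    }
  }
  list(concordant = FALSE, shared_allele = NA_character_)
}

gt_dose <- function(geno) {
  d <- rep(NA_integer_, length(geno))
  d[geno == "0/0"] <- 0L
  d[geno %in% c("0/1", "1/0")] <- 1L
  d[geno == "1/1"] <- 2L
  d
}

# position that bounds a variant on the right (END for DUP records)
variant_right_pos <- function(variants) {
  ifelse(variants$vtype == "DUP" & !is.na(variants$end),
         variants$end, variants$pos)
}

#' Scan for maximal case-shared (IBD) intervals
#'
#' Finds maximal runs of consecutive case-concordant polymorphic sites
#' within a candidate interval. Each run is reported from the position of
#' its first concordant site to the last concordant site (using the END
#' coordinate for duplication records), together with the nearest
#' discordant site on either side.
#'
#' @param gm A `crest_genotypes` matrix.
#' @param candidate [genomic_interval()] to scan.
#' @inheritParams site_concordance
#' @return Data.frame of class `ibd_intervals`, sorted by length
#'   descending: `start`, `end`, `length`, `n_support_sites`,
#'   `flank_discordant_left`, `flank_discordant_right`.
#' @export
shared_interval_scan <- function(gm, candidate,
                                 mode = c("homozygous_ibd",
                                          "dominant_carrier"),
                                 pool_fix_threshold = 0.95,
                                 missing_policy = c("strict", "permissive")) {
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), n_support_sites = integer(0),
                    flank_discordant_left = integer(0),
                    flank_discordant_right = integer(0))
  class(out) <- c("ibd_intervals", "data.frame")
  keep <- gm$variants$pos >= candidate$start & gm$variants$pos <= candidate$end
  if (!any(keep)) return(out)
  idx <- which(keep)
  is_case <- gm$samples$phenotype != "non_crested"
  if (!any(is_case)) stop("no case samples")
  is_pool <- gm$samples$sample_kind == "pool"

  conc <- vapply(idx, function(j) {
    site_concordance(gm$geno[j, ], gm$af[j, ], is_case, is_pool, mode,
                     pool_fix_threshold, missing_policy)$concordant
  }, logical(1))
  if (!any(conc)) return(out)

  pos <- gm$variants$pos[idx]
  rpos <- variant_right_pos(gm$variants[idx, , drop = FALSE])
  runs <- rle(conc)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    out[nrow(out) + 1L, ] <- list(
      pos[i0], max(rpos[i0:i1]), max(rpos[i0:i1]) - pos[i0] + 1L,
      i1 - i0 + 1L,
      if (i0 > 1L) pos[i0 - 1L] else NA_integer_,
      if (i1 < length(pos)) pos[i1 + 1L] else NA_integer_)
  }
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ibd_intervals", "data.frame")
  out
}

#' Filter variants for full phenotype concordance
#'
#' Within an interval, keeps variants whose non-reference allele is carried
#' by every crested sample and by no non-crested sample — the rule that
#' singles out the causal candidate among the shared-haplotype changes.
#' Pools count as carriers at or above `pool_fix_threshold` and as
#' non-carriers only at frequency 0.
#'
#' @param gm A `crest_genotypes` matrix.
#' @param interval [genomic_interval()] (e.g. the top scan hit).
#' @param pool_fix_threshold Pool fixation threshold (default 0.95).
#' @return Data.frame of class `candidate_variants`: the variant columns
#'   plus `case_carrier_fraction` and `control_carrier_fraction`
#'   (1 and 0 by construction for returned rows).
#' @export
concordance_filter <- function(gm, interval, pool_fix_threshold = 0.95) {
  v <- gm$variants
  keep <- v$pos >= interval$start & v$pos <= interval$end
  is_case <- gm$samples$phenotype != "non_crested"
  is_pool <- gm$samples$sample_kind == "pool"
  rows <- lapply(which(keep), function(j) {
    dose <- gt_dose(gm$geno[j, ])
    carries <- ifelse(is_pool,
                      gm$af[j, ] >= ifelse(is_case, pool_fix_threshold,
                                           .Machine$double.eps),
                      dose >= 1L)
    cf <- mean(carries[is_case])
    uf <- mean(carries[!is_case])
    cbind(v[j, , drop = FALSE],
          data.frame(case_carrier_fraction = cf,
                     control_carrier_fraction = uf))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(v[0, , drop = FALSE],
                 data.frame(case_carrier_fraction = numeric(0),
                            control_carrier_fraction = numeric(0)))
  }
  out <- out[!is.na(out$case_carrier_fraction) &
               out$case_carrier_fraction == 1 &
               out$control_carrier_fraction == 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_variants", "data.frame")
  out
}

#' Write IBD intervals as BED
#'
#' BED uses 0-based half-open coordinates; conversion goes through
#' [to_zero_based()].
#'
#' @param intervals `ibd_intervals` data.frame.
#' @param chrom Chromosome name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibd_bed <- function(intervals, chrom, path) {
  z <- to_zero_based(intervals$start, intervals$end)
  writeLines(sprintf("%s\t%d\t%d\tibd_%d\t%d", chrom, z$start, z$end,
                     seq_len(nrow(intervals)), intervals$n_support_sites),
             path)
  invisible(path)
}
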