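#' Coordinate constants of the Crest locus model
#'
#' Fixed GalGal6 coordinates preserved by the synthetic reference: the
#' candidate region on chromosome 33, the 197 bp duplication unit, the
#' Cr2-defining C>A site, the (TG)7 microsatellite, the four SNVs that mark
#' the shared crest haplotype, and the diagnostic primer pair with its
#' wild-type amplicon footprint.
#'
#' @return Named list of coordinates, primer sequences and derived offsets.
#' @export
crest_coords <- function() {
  region_start <- 7500000L
  unit_start <- 7587588L
  unit_end <- 7587784L
  primer_f <- "ACCAAACCGCTTCGATGTGT" # Cr_197_F1
  primer_r <- "CGTCCCATTGGCATCACC"   # Cr_197_R1
  # Primer sites are spaced so the single-copy amplicon is 241 bp; on a
  # duplicated template the extra unit copy makes the product length emerge.
  fwd_site_start <- unit_start - 22L                 # 20 bp primer + 2 bp gap
  rev_site_end <- unit_end + 22L                     # 4 bp gap + 18 bp primer
  list(
    chrom = "chr33",
    region_start = region_start,
    region_end = 7820000L,
    candidate_start = 7570000L,    # 7.57 Mb marker HOXC-SCF2
    candidate_end = 7820000L,      # distal end of chromosome 33, 7.82 Mb
    unit_start = unit_start,
    unit_end = unit_end,
    unit_length = unit_end - unit_start + 1L,        # 197 bp
    snp_pos = 7587629L,            # g.7,587,629C>A (Cr2)
    tg_pos = 7587694L,             # (TG)7 run start (Cr3 expands to (TG)8)
    tg_units_wt = 7L,
    ibd_snvs = c(7586870L, 7586999L, 7587089L, 7587313L),
    ibd_start = 7585881L,          # 5' IBD boundary marker
    primer_f = primer_f,
    primer_r = primer_r,
    fwd_site_start = fwd_site_start,
    fwd_site_end = fwd_site_start + nchar(primer_f) - 1L,
    rev_site_start = rev_site_end - nchar(primer_r) + 1L,
    rev_site_end = rev_site_end,
    wt_amplicon = rev_site_end - fwd_site_start + 1L # 241 bp
  )
}

#' Candidate region harbouring the Crest locus
#'
#' The 250 kb interval on chromosome 33 from the proximal linkage marker at
#' 7.57 Mb to the distal chromosome end at 7.82 Mb.
#'
#' @return A [genomic_interval()].
#' @export
crest_candidate_region <- function() {
  co <- crest_coords()
  genomic_interval(co$chrom, co$candidate_start, co$candidate_end)
}

# genomic position -> index into the reference sequence string
g2i <- function(ref, g) as.integer(g) - ref$region$start + 1L

#' Build the synthetic reference model of the Crest candidate region
#'
#' Generates a seeded random nucleotide sequence for chr33:7,500,000-7,820,000
#' with the locus features planted at their true GalGal6 coordinates: the
#' 197 bp duplication unit (containing base C at 7,587,629 and a perfect
#' (TG)7 run at 7,587,694), and the diagnostic primer sites spaced so the
#' wild-type amplicon is 241 bp. After planting, any other exact occurrence
#' of either primer (both strands) is destroyed genome-wide, and any other
#' (TG)>=6 run within 5 kb of the unit is broken, so primer matching and
#' microsatellite typing are unambiguous. The base immediately before the
#' unit is forced to differ from the unit's last base, giving the tandem
#' junction zero microhomology.
#'
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return An object of class `crest_reference` with elements `region`
#'   (a [genomic_interval()]), `sequence` (character scalar), `coords`
#'   (from [crest_coords()]) and `seed`.
#' @export
build_reference <- function(seed = 1L) {
  co <- crest_coords()
  L <- co$region_end - co$region_start + 1L
  idx <- function(g) g - co$region_start + 1L
  bases <- c("A", "C", "G", "T")
  s <- withr::with_seed(seed, sample(bases, L, replace = TRUE))

  # plant unit-internal features
  s[idx(co$snp_pos)] <- "C"
  s[idx(co$tg_pos) + 0:13] <- rep(c("T", "G"), co$tg_units_wt)
  s[idx(co$tg_pos) - c(2L, 1L)] <- c("C", "A")  # block leftward run extension
  s[idx(co$tg_pos) + c(14L, 15L)] <- c("A", "C") # block rightward extension

  # plant primer sites flanking the unit
  f <- strsplit(co$primer_f, "")[[1]]
  rrc <- strsplit(revcomp(co$primer_r), "")[[1]]
  s[idx(co$fwd_site_start) + seq_along(f) - 1L] <- f
  s[idx(co$rev_site_start) + seq_along(rrc) - 1L] <- rrc

  # zero microhomology at the planted tandem junction: base before the unit
  # must differ from the unit's last base (the 2 bp gap after the forward
  # primer is free to edit)
  if (s[idx(co$unit_start) - 1L] == s[idx(co$unit_end)]) {
    s[idx(co$unit_start) - 1L] <- setdiff(bases, s[idx(co$unit_end)])[1L]
  }

  ref <- structure(
    list(region = genomic_interval(co$chrom, co$region_start, co$region_end),
         sequence = paste(s, collapse = ""),
         coords = co, seed = seed),
    class = "crest_reference")
  ref$sequence <- scrub_stray_features(ref)
  ref
}

# Remove accidental primer matches (whole region, both strands) and
# accidental (TG)>=6 runs within 5 kb of the unit. Edits are deterministic
# single-base substitutions; iterate until stable.
scrub_stray_features <- function(ref) {
  co <- ref$coords
  seq <- ref$sequence
  keep <- list( # planted footprints that must not be edited
    c(g2i(ref, co$fwd_site_start), g2i(ref, co$fwd_site_end)),
    c(g2i(ref, co$rev_site_start), g2i(ref, co$rev_site_end)),
    c(g2i(ref, co$tg_pos), g2i(ref, co$tg_pos) + 13L))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in 1:10) {
    subject <- Biostrings::DNAString(seq)
    hit_mid <- integer(0)
    for (p in c(co$primer_f, co$primer_r, revcomp(co$primer_f),
                revcomp(co$primer_r))) {
      m <- Biostrings::matchPattern(p, subject)
      if (length(m)) {
        hit_mid <- c(hit_mid, Biostrings::start(m) +
                       (nchar(p) %/% 2L))
      }
    }
    tg6 <- strrep("TG", 6L)
    win_lo <- max(1L, g2i(ref, co$unit_start) - 5000L)
    win_hi <- min(nchar(seq), g2i(ref, co$unit_end) + 5000L)
    mtg <- Biostrings::matchPattern(
      tg6, Biostrings::subseq(subject, win_lo, win_hi))
    if (length(mtg)) {
      hit_mid <- c(hit_mid, Biostrings::start(mtg) + win_lo - 1L + 5L)
    }
    protected <- vapply(hit_mid, function(i) {
      any(vapply(keep, function(k) i >= k[1] - 24L && i <= k[2] + 24L,
                 logical(1)))
    }, logical(1))
    hit_mid <- unique(hit_mid[!protected])
    if (!length(hit_mid)) break
    for (i in hit_mid) {
      substr(seq, i, i) <- rot[[substr(seq, i, i)]]
    }
  }
  seq
}

#' @export
print.crest_reference <- function(x, ...) {
  cat("Crest-locus synthetic reference (seed", x$seed, ")\n")
  print(x$region)
  cat(sprintf("  duplication unit %s-%s (%d bp), SNP site %s, (TG)%d at %s\n",
              format(x$coords$unit_start, big.mark = ","),
              format(x$coords$unit_end, big.mark = ","),
              x$coords$unit_length,
              format(x$coords$snp_pos, big.mark = ","),
              x$coords$tg_units_wt,
              format(x$coords$tg_pos, big.mark = ",")))
  invisible(x)
}

#' Extract reference sequence for a genomic range
#' @param ref A `crest_reference`.
#' @param start,end 1-based genomic coordinates within the modelled region.
#' @return Character scalar.
#' @export
ref_slice <- function(ref, start, end) {
  stopifnot(start >= ref$region$start, end <= ref$region$end, end >= start)
  substr(ref$sequence, g2i(ref, start), g2i(ref, end))
}

#' The five Crest-locus allele specifications
#'
#' Structural definitions of the alleles: `crWT` (single copy, C, (TG)7),
#' `Cr1` (tandem duplication, both copies C/(TG)7), `Cr2` (duplication with
#' the C>A substitution in the 3' copy), `Cr3` (duplication with the
#' (TG)7 -> (TG)8 expansion in the 5' copy) and `Cr2_backmutant` (single copy
#' carrying the A base, the haplotype inferred to derive from Cr2 by loss of
#' one copy, found in non-crested Ameraucana).
#'
#' @param name Optional allele name; if given, return that single spec.
#' @return A named list of allele specs (or one spec): each has
#'   `name`, `has_duplication`, `snp_base_5prime`, `snp_base_3prime`
#'   (single-copy alleles use the 3' slot), `tg_5prime`, `tg_3prime`.
#' @export
crest_alleles <- function(name = NULL) {
  spec <- function(nm, dup, s5, s3, t5, t3) {
    list(name = nm, has_duplication = dup,
         snp_base_5prime = s5, snp_base_3prime = s3,
         tg_5prime = t5, tg_3prime = t3)
  }
  all <- list(
    crWT = spec("crWT", FALSE, NA_character_, "C", NA_integer_, 7L),
    Cr1 = spec("Cr1", TRUE, "C", "C", 7L, 7L),
    Cr2 = spec("Cr2", TRUE, "C", "A", 7L, 7L),
    Cr3 = spec("Cr3", TRUE, "C", "C", 8L, 7L),
    Cr2_backmutant = spec("Cr2_backmutant", FALSE, NA_character_, "A",
                          NA_integer_, 7L))
  if (is.null(name)) return(all)
  if (!name %in% names(all)) stop("unknown Crest allele: ", name)
  all[[name]]
}

#' Build a haplotype of the Crest locus region
#'
#' Constructs the full-region haplotype implied by an allele spec: duplicated
#' alleles insert a second tandem copy of the 197 bp unit immediately after
#' the original; the Cr2 substitution is applied to the 3' copy, the Cr3
#' (TG)8 expansion to the 5' copy. The returned haplotype carries a block
#' map recording, for every haplotype base, its reference origin — the read
#' simulator places reads analytically from this map.
#'
#' @param ref A `crest_reference`.
#' @param allele Allele name (see [crest_alleles()]) or a spec list.
#' @return Object of class `crest_haplotype`: `allele`, `blocks`
#'   (data.frame `hstart`, `len`, `rstart` with NA for inserted bases, `ins`
#'   inserted sequence), `hsubs` (haplotype-coordinate substitutions),
#'   `length`.
#' @export
build_allele <- function(ref, allele) {
  spec <- if (is.character(allele)) crest_alleles(allele) else allele
  co <- ref$coords
  L <- gi_length(ref$region)
  iu1 <- g2i(ref, co$unit_start)
  iu2 <- g2i(ref, co$unit_end)
  snp_off <- co$snp_pos - co$unit_start + 1L   # 42
  tg_off <- co$tg_pos - co$unit_start + 1L     # 107
  tg_end_off <- tg_off + 2L * co$tg_units_wt - 1L # 120

  blocks <- data.frame(hstart = integer(0), len = integer(0),
                       rstart = integer(0), ins = character(0),
                       stringsAsFactors = FALSE)
  add <- function(len, rstart, ins = NA_character_) {
    hstart <- if (nrow(blocks)) blocks$hstart[nrow(blocks)] +
      blocks$len[nrow(blocks)] else 1L
    blocks[nrow(blocks) + 1L, ] <<- list(hstart, as.integer(len),
                                         rstart, ins)
  }
  hsubs <- data.frame(hpos = integer(0), base = character(0),
                      stringsAsFactors = FALSE)
  sub_at <- function(hpos, base) {
    hsubs[nrow(hsubs) + 1L, ] <<- list(as.integer(hpos), base)
  }

  if (!spec$has_duplication) {
    add(L, ref$region$start)
    if (spec$snp_base_3prime != "C") sub_at(iu1 + snp_off - 1L,
                                            spec$snp_base_3prime)
    if (spec$tg_3prime != co$tg_units_wt)
      stop("single-copy alleles with expanded TG runs are not modelled")
  } else {
    if (spec$tg_5prime > co$tg_units_wt) {
      # 5' copy carries the expanded run: insertion after the run end
      extra <- 2L * (spec$tg_5prime - co$tg_units_wt)
      add(iu1 + tg_end_off - 1L, ref$region$start) # through run end in copy 1
      add(extra, NA_integer_, strrep("TG", spec$tg_5prime - co$tg_units_wt))
      add(iu2 - (iu1 + tg_end_off - 1L), co$tg_pos + 2L * co$tg_units_wt)
    } else {
      add(iu2, ref$region$start)                   # through end of copy 1
    }
    copy2_hstart <- blocks$hstart[nrow(blocks)] + blocks$len[nrow(blocks)]
    add(co$unit_length, co$unit_start)             # tandem second copy
    add(L - iu2, co$unit_end + 1L)                 # suffix
    # copy-specific substitutions
    if (spec$snp_base_5prime != "C") sub_at(iu1 + snp_off - 1L,
                                            spec$snp_base_5prime)
    if (spec$snp_base_3prime != "C") sub_at(copy2_hstart + snp_off - 1L,
                                            spec$snp_base_3prime)
    if (spec$tg_3prime != co$tg_units_wt)
      stop("3'-copy TG expansion is not part of any modelled allele")
  }

  structure(list(allele = spec$name, blocks = blocks, hsubs = hsubs,
                 length = sum(blocks$len)),
            class = "crest_haplotype")
}

#' Add extra SNVs (genomic coordinates) to a haplotype
#'
#' Used by the cohort generator for background variation, boundary markers
#' and the four shared-haplotype SNVs. Positions must fall outside the
#' duplication unit, where the genomic-to-haplotype map is unique.
#'
#' @param hap A `crest_haplotype`.
#' @param pos Integer genomic positions.
#' @param base Replacement bases (recycled if length 1).
#' @return The modified haplotype.
#' @export
hap_add_snvs <- function(hap, pos, base) {
  if (!length(pos)) return(hap)
  base <- rep_len(base, length(pos))
  hp <- vapply(pos, function(g) g2h(hap, g), integer(1))
  hap$hsubs <- rbind(hap$hsubs,
                     data.frame(hpos = hp, base = base,
                                stringsAsFactors = FALSE))
  hap
}

# genomic position -> haplotype position (first matching block)
g2h <- function(hap, g) {
  b <- hap$blocks
  for (i in seq_len(nrow(b))) {
    if (!is.na(b$rstart[i]) && g >= b$rstart[i] && g < b$rstart[i] + b$len[i])
      return(b$hstart[i] + as.integer(g - b$rstart[i]))
  }
  stop("genomic position ", g, " not represented on haplotype")
}

#' Materialize a haplotype sequence
#'
#' @param ref A `crest_reference`.
#' @param hap A `crest_haplotype`.
#' @return Character scalar of length `hap$length`.
#' @export
hap_sequence <- function(ref, hap) {
  b <- hap$blocks
  pieces <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    pieces[i] <- if (is.na(b$rstart[i])) b$ins[i] else
      substr(ref$sequence, g2i(ref, b$rstart[i]),
             g2i(ref, b$rstart[i]) + b$len[i] - 1L)
  }
  s <- paste(pieces, collapse = "")
  n_sub <- nrow(hap$hsubs)
  if (n_sub > 8L) {
    # bulk path: per-base substitution via a character vector; repeated
    # substr<- on a multi-hundred-kb string copies it each time
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    v[hap$hsubs$hpos] <- hap$hsubs$base
    s <- paste(v, collapse = "")
  } else {
    for (j in seq_len(n_sub)) {
      substr(s, hap$hsubs$hpos[j], hap$hsubs$hpos[j]) <- hap$hsubs$base[j]
    }
  }
  s
}

#' @export
print.crest_haplotype <- function(x, ...) {
  cat(sprintf("Crest haplotype %s: %d bp, %d block(s), %d extra SNV(s)\n",
              x$allele, x$length, nrow(x$blocks), nrow(x$hsubs)))
  invisible(x)
}
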