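#' Cohort designs
#'
#' A design is a data.frame with one row per sample group: `breed`,
#' `phenotype`, `allele_a`, `allele_b` (diploid genotype over the five
#' Crest alleles), `n` (number of samples), `sample_kind` and `pool_size`
#' (birds per pool; NA for individuals), plus attributes controlling the
#' generator (`bg_sites`, `wt_ibd_carrier_frac`).
#'
#' `wgs_panel_design()` emulates the whole-genome re-sequencing panel used
#' for the identity-by-descent scan: 22 crested samples (18 individuals and
#' 4 pools of 10 birds, all homozygous for duplication alleles) plus 197
#' non-crested individuals. `table1_design()` reproduces the diagnostic
#' cohort summarised per breed (54 crested and 433 non-crested birds).
#'
#' @return A `crest_design` data.frame.
#' @export
wgs_panel_design <- function() {
  g <- function(breed, phen, a, b, n, kind = "individual", pool = NA_integer_)
    data.frame(breed = breed, phenotype = phen, allele_a = a, allele_b = b,
               n = n, sample_kind = kind, pool_size = pool,
               stringsAsFactors = FALSE)
  d <- rbind(
    g("Silkie", "crested_small", "Cr1", "Cr1", 5L),
    g("Beijing You", "crested_small", "Cr1", "Cr1", 1L),
    g("Crested Dutch", "crested_large", "Cr2", "Cr2", 1L),
    g("Houdan", "crested_large", "Cr2", "Cr2", 3L),
    g("Polish", "crested_large", "Cr2", "Cr2", 3L),
    g("Dutch-Polish", "crested_large", "Cr3", "Cr3", 2L),
    g("Appenzeller", "crested_upward", "Cr2", "Cr2", 2L),
    g("Schijndelaar", "crested_upward", "Cr2", "Cr3", 1L),
    g("Silkie", "crested_small", "Cr1", "Cr1", 1L, "pool", 10L),
    g("Polish", "crested_large", "Cr2", "Cr2", 1L, "pool", 10L),
    g("Houdan", "crested_large", "Cr2", "Cr2", 1L, "pool", 10L),
    g("Dutch-Polish", "crested_large", "Cr3", "Cr3", 1L, "pool", 10L),
    g("Other breeds", "non_crested", "crWT", "crWT", 197L))
  new_design(d)
}

#' @rdname wgs_panel_design
#' @export
table1_design <- function() {
  g <- function(breed, phen, a, b, n)
    data.frame(breed = breed, phenotype = phen, allele_a = a, allele_b = b,
               n = n, sample_kind = "individual", pool_size = NA_integer_,
               stringsAsFactors = FALSE)
  d <- rbind(
    g("Beijing You", "crested_small", "Cr1", "Cr1", 1L),
    g("Silkie", "crested_small", "Cr1", "Cr1", 22L),
    g("Crested Dutch", "crested_large", "Cr2", "Cr2", 1L),
    g("Crevecoeur", "crested_large", "Cr2", "Cr2", 1L),
    g("Dutch-Polish", "crested_large", "Cr2", "Cr2", 3L),
    g("Dutch-Polish", "crested_large", "Cr2", "Cr3", 1L),
    g("Dutch-Polish", "crested_large", "Cr3", "Cr3", 4L),
    g("Houdan", "crested_large", "Cr2", "Cr2", 8L),
    g("Polish", "crested_large", "Cr2", "Cr2", 11L),
    g("Polish", "crested_large", "Cr2", "Cr3", 2L),
    g("Polish", "crested_large", "Cr3", "Cr3", 1L),
    g("Sultan", "crested_large", "Cr2", "Cr2", 5L),
    g("Sultan", "crested_large", "Cr3", "Cr3", 2L),
    g("Appenzeller", "crested_upward", "Cr2", "Cr2", 4L),
    g("Schijndelaar", "crested_upward", "Cr2", "Cr2", 1L),
    g("Schijndelaar", "crested_upward", "Cr2", "Cr3", 1L),
    g("Other breeds", "non_crested", "crWT", "crWT", 433L))
  new_design(d)
}

new_design <- function(d, bg_sites = 160L, wt_ibd_carrier_frac = 0.05) {
  stopifnot(all(d$n >= 0),
            all(c(d$allele_a, d$allele_b) %in% names(crest_alleles())))
  attr(d, "bg_sites") <- bg_sites
  attr(d, "wt_ibd_carrier_frac") <- wt_ibd_carrier_frac
  class(d) <- c("crest_design", "data.frame")
  d
}

DUP_ALLELES <- c("Cr1", "Cr2", "Cr3")

#' Generate the synthetic cohort
#'
#' Expands a design into samples with haplotype pairs, places the truth
#' variants and returns the genotype matrix. The construction mirrors the
#' shared-haplotype logic of the mapping study:
#'
#' * every duplication-bearing haplotype carries the four shared-haplotype
#'   SNVs (7,586,870 / 7,586,999 / 7,587,089 / 7,587,313); a minority
#'   (default 5%, at least one when possible) of wild-type haplotypes also
#'   carries them, so the SNVs are shared by all cases yet fail the
#'   phenotype-concordance filter;
#' * a boundary marker at 7,585,881 where all case haplotypes carry the
#'   reference allele while controls segregate, plus further such markers
#'   outside the shared interval;
#' * the polymorphic sites immediately flanking 7,585,881 and 7,587,784 are
#'   forced case-discordant;
#' * background SNVs at random positions outside the locus window, with
#'   population frequencies drawn uniformly on (0.1, 0.9).
#'
#' Within 7,585,881-7,587,784 a case haplotype therefore differs from the
#' reference at exactly the four SNVs plus the duplication.
#'
#' @param ref A `crest_reference`.
#' @param design A `crest_design` (default [wgs_panel_design()]).
#' @param seed Integer seed.
#' @return List of class `crest_cohort`: `samples` (sample sheet),
#'   `matrix` (`crest_genotypes`), `haplotypes` (per sample, a list of
#'   `crest_haplotype`; two per individual, `2 * pool_size` per pool),
#'   `design`, `seed`.
#' @export
generate_cohort <- function(ref, design = wgs_panel_design(), seed = 1L) {
  co <- ref$coords
  bad <- design$allele_a == "Cr2_backmutant" &
    design$allele_b == "Cr2_backmutant" &
    design$phenotype != "non_crested" & design$n > 0
  if (any(bad)) {
    stop("back-mutant homozygous crested individuals are contradictory: ",
         "the back-mutant haplotype lacks the duplication")
  }
  design <- design[design$n > 0, , drop = FALSE]

  # expand design rows into samples
  samples <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    r <- design[i, ]
    data.frame(breed = r$breed, phenotype = r$phenotype,
               allele_a = r$allele_a, allele_b = r$allele_b,
               sample_kind = r$sample_kind,
               pool_size = r$pool_size, stringsAsFactors = FALSE)[
                 rep(1L, r$n), , drop = FALSE]
  }))
  empty <- is.null(samples) || nrow(samples) == 0L
  if (!empty) {
    rownames(samples) <- NULL
    samples$sample_id <- sprintf("%s_%03d",
                                 gsub("[^A-Za-z0-9]+", "", samples$breed),
                                 stats::ave(seq_len(nrow(samples)),
                                            samples$breed, FUN = seq_along))
  }

  withr::with_seed(seed, {
    # per-sample haplotype allele lists
    hap_alleles <- if (empty) list() else lapply(seq_len(nrow(samples)),
                                                 function(i) {
      k <- if (samples$sample_kind[i] == "pool") samples$pool_size[i] else 1L
      rep(c(samples$allele_a[i], samples$allele_b[i]), k)
    })
    all_alleles <- unlist(hap_alleles)
    n_hap <- length(all_alleles)
    is_wt_hap <- all_alleles == "crWT"

    # which wild-type haplotypes carry the four shared-haplotype SNVs
    frac <- attr(design, "wt_ibd_carrier_frac")
    if (is.null(frac)) frac <- 0.05
    wt_carrier <- rep(FALSE, n_hap)
    if (any(is_wt_hap) && frac > 0) {
      k <- max(1L, stats::rbinom(1L, sum(is_wt_hap), frac))
      wt_carrier[sample(which(is_wt_hap), k)] <- TRUE
    }
    # duplication-bearing and back-mutant haplotypes carry them by descent
    ibd_carrier <- all_alleles %in% c(DUP_ALLELES, "Cr2_backmutant") |
      wt_carrier

    # variant site table ------------------------------------------------
    n_bg <- attr(design, "bg_sites")
    if (is.null(n_bg)) n_bg <- 160L
    excl_lo <- 7585500L; excl_hi <- 7588000L   # locus window: no background
    bg_pos <- sort(sample(setdiff(
      seq(ref$region$start + 1000L, ref$region$end - 1000L, by = 13L),
      excl_lo:excl_hi), n_bg))
    sites <- data.frame(
      pos = bg_pos, kind = "background",
      freq = stats::runif(n_bg, 0.1, 0.9), stringsAsFactors = FALSE)
    # forced case-discordant sites immediately flanking the shared interval
    sites <- rbind(sites,
                   data.frame(pos = c(7585820L, 7587900L),
                              kind = "flank_discordant", freq = 0.5),
                   data.frame(pos = co$ibd_start,
                              kind = "boundary_marker", freq = 0.3),
                   data.frame(pos = c(7580000L, 7600000L),
                              kind = "boundary_marker", freq = 0.3),
                   data.frame(pos = co$ibd_snvs, kind = "ibd_snv",
                              freq = NA_real_))
    sites <- sites[order(sites$pos), , drop = FALSE]
    rownames(sites) <- NULL

    sample_of_hap <- if (n_hap) {
      rep(seq_len(nrow(samples)), lengths(hap_alleles))
    } else integer(0)
    is_case_hap <- if (n_hap) {
      samples$phenotype[sample_of_hap] != "non_crested"
    } else logical(0)
    # the two haplotypes of one case individual, made heterozygous at the
    # forced flanking discordant sites
    case_ind <- if (n_hap) {
      which(samples$phenotype != "non_crested" &
              samples$sample_kind == "individual")
    } else integer(0)
    het_haps <- if (length(case_ind)) which(sample_of_hap == case_ind[1L])
      else integer(0)

    # haplotype x site carrier matrix
    carrier <- matrix(FALSE, nrow(sites), n_hap)
    for (j in seq_len(nrow(sites))) {
      carrier[j, ] <- switch(
        sites$kind[j],
        background = stats::runif(n_hap) < sites$freq[j],
        boundary_marker = ifelse(is_case_hap, FALSE,
                                 stats::runif(n_hap) < sites$freq[j]),
        flank_discordant = {
          v <- stats::runif(n_hap) < sites$freq[j]
          if (length(het_haps) >= 2L) {
            v[het_haps[1L]] <- TRUE
            v[het_haps[2L]] <- FALSE
          }
          v
        },
        ibd_snv = ibd_carrier)
    }
    # background sites where by chance every case haplotype agrees with a
    # fixed control side could mimic sharing; rare, tolerated (the scan is
    # bounded by the forced discordant flanks)

    # alt bases for substitution sites
    alt_of <- function(pos) {
      refb <- ref_slice(ref, pos, pos)
      c(A = "C", C = "T", G = "A", T = "G")[[refb]]
    }
    sites$ref <- vapply(sites$pos, function(p) ref_slice(ref, p, p),
                        character(1))
    sites$alt <- vapply(sites$pos, alt_of, character(1))

    # build haplotype objects --------------------------------------------
    haplotypes <- list()
    if (n_hap) {
      hap_index <- 0L
      haplotypes <- lapply(seq_len(nrow(samples)), function(i) {
        lapply(seq_along(hap_alleles[[i]]), function(k) {
          hap_index <<- hap_index + 1L
          h <- build_allele(ref, hap_alleles[[i]][k])
          snv_pos <- sites$pos[carrier[, hap_index]]
          # the four shared SNVs are intrinsic to back-mutant/duplication
          # haplotypes: already included via carrier[]
          hap_add_snvs(h, snv_pos, sites$alt[match(snv_pos, sites$pos)])
        })
      })
      names(haplotypes) <- samples$sample_id
    }

    # genotype matrix -----------------------------------------------------
    sheet <- if (empty) {
      data.frame(sample_id = character(0), breed = character(0),
                 phenotype = character(0), sample_kind = character(0),
                 stringsAsFactors = FALSE)
    } else samples[c("sample_id", "breed", "phenotype", "sample_kind")]

    has_dup <- all_alleles %in% DUP_ALLELES
    variants <- rbind(
      data.frame(chrom = co$chrom, pos = sites$pos,
                 id = sprintf("site_%d", sites$pos), ref = sites$ref,
                 alt = sites$alt, vtype = "SNV", end = NA_integer_,
                 stringsAsFactors = FALSE),
      data.frame(chrom = co$chrom, pos = co$unit_start, id = "crest_dup",
                 ref = substr(ref$sequence, g2i(ref, co$unit_start),
                              g2i(ref, co$unit_start)),
                 alt = "<DUP>", vtype = "DUP", end = co$unit_end,
                 stringsAsFactors = FALSE))
    carrier_full <- rbind(carrier, has_dup)

    geno <- matrix(NA_character_, nrow(variants), max(1L, nrow(sheet)))
    af <- matrix(NA_real_, nrow(variants), max(1L, nrow(sheet)))
    if (!empty) {
      hap_of_sample <- split(seq_len(n_hap),
                             rep(seq_len(nrow(samples)),
                                 lengths(hap_alleles)))
      for (i in seq_len(nrow(samples))) {
        hx <- hap_of_sample[[i]]
        dose <- rowSums(carrier_full[, hx, drop = FALSE])
        if (samples$sample_kind[i] == "pool") {
          af[, i] <- dose / length(hx)
        } else {
          geno[, i] <- c("0/0", "0/1", "1/1")[dose + 1L]
        }
      }
      gm <- genotype_matrix(variants, sheet, geno, af)
    } else {
      gm <- genotype_matrix(variants[0, , drop = FALSE], sheet,
                            geno[0, 0, drop = FALSE],
                            af[0, 0, drop = FALSE])
    }

    structure(list(samples = sheet, matrix = gm, haplotypes = haplotypes,
                   design = design, seed = seed),
              class = "crest_cohort")
  })
}

#' @export
print.crest_cohort <- function(x, ...) {
  cat(sprintf("Crest synthetic cohort (seed %d): %d sample(s), %d case(s)\n",
              x$seed, nrow(x$samples),
              sum(x$samples$phenotype != "non_crested")))
  print(x$matrix)
  invisible(x)
}

#' Write cohort artifacts (sample sheet + truth VCF)
#'
#' @param cohort A `crest_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    samples = file.path(dir, "samples.tsv"),
    truth_vcf = file.path(dir, "truth.vcf"))
  write_sample_sheet(cohort$samples, paths$samples)
  write_vcf(cohort$matrix, paths$truth_vcf)
  paths
}
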