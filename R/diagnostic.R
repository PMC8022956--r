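#' The diagnostic primer pair for the 197 bp duplication
#'
#' @return List of class `primer_pair` with `forward`, `reverse`, `name`.
#' @export
crest_primers <- function() {
  co <- crest_coords()
  primer_pair(co$primer_f, co$primer_r, "Cr_197")
}

#' @rdname crest_primers
#' @param forward,reverse Primer sequences, 5' to 3'.
#' @param name Assay name.
#' @export
primer_pair <- function(forward, reverse, name = "primer_pair") {
  for (p in c(forward, reverse)) {
    if (!nzchar(p) || grepl("[^ACGT]", p)) {
      stop("primers must be non-empty ACGT sequences")
    }
  }
  structure(list(forward = forward, reverse = reverse, name = name),
            class = "primer_pair")
}

#' In-silico PCR
#'
#' Finds every product a primer pair would amplify from a template:
#' occurrences of one primer followed, within `max_product`, by the
#' reverse complement of the other, on either strand. Matching is exact;
#' the product length counts both primer footprints.
#'
#' @param template Template sequence (character scalar).
#' @param primers A `primer_pair` (default [crest_primers()]).
#' @param max_product Maximum product length in bp (default 5000).
#' @return Data.frame: `start`, `end` (template coordinates, 1-based),
#'   `length`, `seq`. Zero rows when nothing amplifies.
#' @export
insilico_pcr <- function(template, primers = crest_primers(),
                         max_product = 5000L) {
  subject <- Biostrings::DNAString(template)
  hits <- function(p) {
    m <- Biostrings::matchPattern(p, subject)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), seq = character(0),
                    stringsAsFactors = FALSE)
  orientations <- list(c(primers$forward, primers$reverse),
                       c(primers$reverse, primers$forward))
  for (o in orientations) {
    fw <- hits(o[1])
    rc <- hits(revcomp(o[2]))
    for (i in seq_len(nrow(fw))) {
      for (j in seq_len(nrow(rc))) {
        if (rc$start[j] > fw$end[i] &&
            rc$end[j] - fw$start[i] + 1L <= max_product) {
          out[nrow(out) + 1L, ] <- list(
            fw$start[i], rc$end[j], rc$end[j] - fw$start[i] + 1L,
            substr(template, fw$start[i], rc$end[j]))
        }
      }
    }
  }
  out <- unique(out[order(out$start, out$end), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Interpret diagnostic fragment lengths
#'
#' Gel-level genotype from the multiset of product lengths of one
#' individual: the wild-type fragment only is `hom_wt`, the duplication
#' fragment only is `hom_dup`, both is `het`, anything else `fail`.
#' Lengths are matched with a gel tolerance (default +/- 3 bp, so the 2 bp
#' longer Cr3 product still reads as a duplication fragment).
#'
#' @param lengths Integer vector of product lengths (both haplotypes).
#' @param wt_len,dup_len Expected fragment sizes (defaults 241 and 438).
#' @param tol Length tolerance in bp (default 3).
#' @return One of `"hom_dup"`, `"het"`, `"hom_wt"`, `"fail"`.
#' @export
fragment_interpret <- function(lengths, wt_len = 241L, dup_len = 438L,
                               tol = 3L) {
  if (!length(lengths)) return("fail")
  is_wt <- abs(lengths - wt_len) <= tol
  is_dup <- abs(lengths - dup_len) <= tol
  if (any(!is_wt & !is_dup)) return("fail")
  if (any(is_wt) && any(is_dup)) return("het")
  if (any(is_dup)) return("hom_dup")
  "hom_wt"
}

# per-haplotype base at the SNP site; duplicated haplotypes read the 3'
# copy (where the Cr2 substitution resides)
hap_snp_base <- function(seq, ref) {
  call <- classify_allele(seq, ref)
  if (!length(call$snp_bases)) return(NA_character_)
  call$snp_bases[length(call$snp_bases)]
}

#' KASP-style genotype at g.7,587,629
#'
#' The competitive allele-specific PCR assay is modelled as a direct
#' biallelic base call at the SNP; for duplicated haplotypes the base is
#' read from the 3' copy. Fluorescence chemistry is not simulated.
#'
#' @param seq_a,seq_b Haplotype sequences of one individual.
#' @param ref A `crest_reference`.
#' @return `"C/C"`, `"C/A"`, `"A/A"`, or NA when a base cannot be resolved.
#' @export
kasp_genotype <- function(seq_a, seq_b, ref) {
  bases <- c(hap_snp_base(seq_a, ref), hap_snp_base(seq_b, ref))
  if (anyNA(bases) || !all(bases %in% c("C", "A"))) return(NA_character_)
  paste(sort(bases, decreasing = TRUE), collapse = "/")  # C before A
}

#' Run the full diagnostic decision flow on one individual
#'
#' PCR both haplotypes with the published primers, interpret the fragment
#' pattern, then route: samples showing the duplication fragment go to
#' sequence-level classification (per haplotype, the Sanger step); samples
#' with only the wild-type fragment are genotyped by the KASP call, which
#' distinguishes crWT (C) from the back-mutant haplotype (A).
#'
#' @param seq_a,seq_b Haplotype sequences of one individual.
#' @param ref A `crest_reference`.
#' @param sample_id Sample label for the result row.
#' @param tol Gel length tolerance (default 3 bp).
#' @return One-row data.frame of class `diagnostic_result`: `sample_id`,
#'   `fragments` (comma-separated lengths), `frag_class`, `kasp_call`,
#'   `final_genotype`, `rule_trace`.
#' @export
diagnose_individual <- function(seq_a, seq_b, ref, sample_id = NA_character_,
                                tol = 3L) {
  co <- ref$coords
  seqs <- list(seq_a, seq_b)
  prods <- lapply(seqs, insilico_pcr)
  lens <- unlist(lapply(prods, `[[`, "length"))
  frag <- fragment_interpret(lens, wt_len = co$wt_amplicon,
                             dup_len = co$wt_amplicon + co$unit_length,
                             tol = tol)
  trace <- c(sprintf("pcr:%s", paste(sort(unique(lens)), collapse = ",")),
             sprintf("fragments:%s", frag))
  kasp <- NA_character_
  final <- "fail"
  if (frag == "fail") {
    trace <- c(trace, "fail:unexpected fragment pattern")
  } else {
    is_dup_hap <- vapply(prods, function(p) {
      nrow(p) == 1L && abs(p$length - (co$wt_amplicon + co$unit_length)) <= tol
    }, logical(1))
    if (frag == "hom_wt") {
      kasp <- kasp_genotype(seq_a, seq_b, ref)
      trace <- c(trace, sprintf("kasp:%s", kasp))
      if (is.na(kasp)) {
        final <- "fail"
      } else {
        lab <- vapply(seqs, function(s) {
          b <- hap_snp_base(s, ref)
          if (identical(b, "A")) "Cr2_backmutant" else "crWT"
        }, character(1))
        final <- genotype_label(lab[1], lab[2])
      }
    } else {
      labels <- vapply(seq_along(seqs), function(k) {
        if (is_dup_hap[k]) {
          trace <<- c(trace, sprintf("sanger:hap%d", k))
          classify_allele(seqs[[k]], ref)$allele
        } else {
          b <- hap_snp_base(seqs[[k]], ref)
          trace <<- c(trace, sprintf("kasp:hap%d:%s", k, b))
          if (identical(b, "A")) "Cr2_backmutant" else "crWT"
        }
      }, character(1))
      # fragment pattern and per-haplotype classification must agree
      dup_labels <- labels %in% DUP_ALLELES
      if ("unknown" %in% labels || !identical(sum(dup_labels),
                                              sum(is_dup_hap))) {
        final <- "fail"
        trace <- c(trace, "fail:contradictory evidence")
      } else {
        final <- genotype_label(labels[1], labels[2])
      }
    }
  }
  out <- data.frame(sample_id = sample_id,
                    fragments = paste(sort(unique(lens)), collapse = ","),
                    frag_class = frag, kasp_call = kasp,
                    final_genotype = final,
                    rule_trace = paste(trace, collapse = ";"),
                    stringsAsFactors = FALSE)
  class(out) <- c("diagnostic_result", "data.frame")
  out
}

#' Diagnose every individual of a cohort
#'
#' @param cohort A `crest_cohort` (individuals only are diagnosed; pooled
#'   samples have no single diploid genotype).
#' @param ref A `crest_reference`.
#' @return `diagnostic_result` data.frame, one row per individual.
#' @export
diagnose_cohort <- function(cohort, ref) {
  ind <- which(cohort$samples$sample_kind == "individual")
  rows <- lapply(ind, function(i) {
    haps <- cohort$haplotypes[[cohort$samples$sample_id[i]]]
    diagnose_individual(hap_sequence(ref, haps[[1]]),
                        hap_sequence(ref, haps[[2]]), ref,
                        sample_id = cohort$samples$sample_id[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diagnostic_result", "data.frame")
  out
}

#' Breed-by-genotype cohort summary
#'
#' The per-breed genotype count table of the diagnostic survey: rows are
#' breed + phenotype, columns genotype classes, with per-breed totals
#' conserved.
#'
#' @param results `diagnostic_result` data.frame.
#' @param sheet Sample-sheet data.frame.
#' @return Data.frame: `breed`, `phenotype`, one column per genotype,
#'   `total`.
#' @export
cohort_summary <- function(results, sheet) {
  if (!nrow(results)) {
    return(data.frame(breed = character(0), phenotype = character(0),
                      total = integer(0), stringsAsFactors = FALSE))
  }
  m <- merge(results, sheet, by = "sample_id")
  gts <- c("Cr1/Cr1", "Cr2/Cr2", "Cr2/Cr3", "Cr3/Cr3", "crWT/crWT")
  gts <- c(gts, setdiff(sort(unique(m$final_genotype)), gts))
  tab <- table(paste(m$breed, m$phenotype, sep = "\r"),
               factor(m$final_genotype, levels = gts))
  key <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(breed = key[, 1], phenotype = key[, 2],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame.matrix(tab))
  out$total <- rowSums(tab)
  # drop all-zero genotype columns to keep the table readable
  keep <- c(TRUE, TRUE, colSums(tab) > 0, TRUE)
  out <- out[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}
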