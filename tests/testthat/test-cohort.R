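test_that("truth matrix and haplotypes tell the same story", {
  ch <- fixture_mini_cohort()
  gm <- ch$matrix
  v <- gm$variants
  ref <- fixture_ref(1)
  dup_row <- which(v$vtype == "DUP")
  set.seed(21)
  for (i in sample(which(ch$samples$sample_kind == "individual"), 6)) {
    haps <- ch$haplotypes[[ch$samples$sample_id[i]]]
    # duplication dosage from the allele structure
    dose_dup <- sum(vapply(haps, function(h)
      h$allele %in% c("Cr1", "Cr2", "Cr3"), logical(1)))
    expect_equal(crestmap:::gt_dose(gm$geno[dup_row, i]), dose_dup)
    # SNV dosage from the haplotype substitution lists
    for (j in sample(which(v$vtype == "SNV"), 8)) {
      dose_snv <- sum(vapply(haps, function(h) {
        hp <- crestmap:::g2h(h, v$pos[j])
        any(h$hsubs$hpos == hp & h$hsubs$base == v$alt[j])
      }, logical(1)))
      expect_equal(crestmap:::gt_dose(gm$geno[j, i]), dose_snv)
    }
  }
})

test_that("the shared interval contains exactly the five case changes", {
  ch <- fixture_wgs_cohort()
  v <- ch$matrix$variants
  inside <- v[v$pos >= 7585881 & v$pos <= 7587784, ]
  # boundary marker (cases reference) + 4 SNVs + DUP
  expect_equal(nrow(inside), 6L)
  case_cols <- ch$samples$phenotype != "non_crested" &
    ch$samples$sample_kind == "individual"
  case_alt <- vapply(seq_len(nrow(v)), function(j)
    all(crestmap:::gt_dose(ch$matrix$geno[j, case_cols]) == 2L), logical(1))
  changes <- v[case_alt & v$pos >= 7585881 & v$pos <= 7587784, ]
  expect_equal(nrow(changes), 5L)
  expect_setequal(changes$pos[changes$vtype == "SNV"],
                  c(7586870L, 7586999L, 7587089L, 7587313L))
  expect_equal(changes$pos[changes$vtype == "DUP"], 7587588L)
})

test_that("the four shared SNVs also ride on a minority of wild-type haplotypes", {
  ch <- fixture_wgs_cohort()
  gm <- ch$matrix
  ctrl <- gm$samples$phenotype == "non_crested"
  snv_rows <- match(sprintf("site_%d", c(7586870L, 7586999L, 7587089L,
                                         7587313L)), gm$variants$id)
  for (j in snv_rows) {
    doses <- crestmap:::gt_dose(gm$geno[j, ctrl])
    frac <- sum(doses, na.rm = TRUE) / (2 * sum(!is.na(doses)))
    expect_gt(frac, 0)       # shared by some controls: not concordant
    expect_lt(frac, 0.2)     # but clearly a minority
  }
})

test_that("an empty design yields an empty cohort and matrix", {
  d <- mini_panel_design()
  d$n <- 0L
  ch <- generate_cohort(fixture_ref(1), d, seed = 1)
  expect_equal(nrow(ch$samples), 0L)
  expect_equal(dim(ch$matrix), c(0L, 0L))
  expect_length(ch$haplotypes, 0L)
})

test_that("a fixed case pool has alt frequency 1 at the duplication", {
  g <- data.frame(breed = c("Silkie", "ctrl"),
                  phenotype = c("crested_small", "non_crested"),
                  allele_a = c("Cr1", "crWT"), allele_b = c("Cr1", "crWT"),
                  n = c(1L, 2L), sample_kind = c("pool", "individual"),
                  pool_size = c(20L, NA_integer_))
  ch <- generate_cohort(fixture_ref(1), crestmap:::new_design(g), seed = 4)
  gm <- ch$matrix
  pool_col <- gm$samples$sample_kind == "pool"
  dup_row <- gm$variants$vtype == "DUP"
  expect_equal(unname(gm$af[dup_row, pool_col]), 1.0)
  expect_true(all(is.na(gm$geno[, pool_col])))
  expect_true(all(is.na(gm$af[, !pool_col])))
})

test_that("crested back-mutant homozygotes are rejected as contradictory", {
  d <- data.frame(breed = "X", phenotype = "crested_large",
                  allele_a = "Cr2_backmutant", allele_b = "Cr2_backmutant",
                  n = 1L, sample_kind = "individual",
                  pool_size = NA_integer_)
  expect_error(generate_cohort(fixture_ref(1), crestmap:::new_design(d)),
               "contradictory")
})

test_that("error-free reads reproduce the reference through the coordinate map", {
  ref <- fixture_ref(1)
  h1 <- build_allele(ref, "Cr1")   # no sequence edits, pure duplication
  region <- genomic_interval("chr33", 7587000L, 7588500L)
  aln <- simulate_alignments(ref, list(h1, h1), coverage = 8,
                             region = region, seed = 6)
  prim <- aln[bitwAnd(aln$flag, 2048L) == 0L, ]
  full <- prim[prim$cigar == "100M", ]
  expect_gt(nrow(full), 20)
  for (i in seq_len(nrow(full))) {
    expect_equal(full$seq[i], ref_slice(ref, full$pos[i], full$pos[i] + 99L))
  }
})

test_that("cohort generation is deterministic per seed", {
  d <- mini_panel_design(n_controls = 6L)
  a <- generate_cohort(fixture_ref(1), d, seed = 12)
  b <- generate_cohort(fixture_ref(1), d, seed = 12)
  expect_identical(a$matrix$geno, b$matrix$geno)
  expect_identical(a$matrix$af, b$matrix$af)
  c2 <- generate_cohort(fixture_ref(1), d, seed = 13)
  expect_false(identical(a$matrix$geno, c2$matrix$geno))
})
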