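test_that("primer pairs validate their sequences", {
  expect_error(primer_pair("ACGT", ""), "ACGT")
  expect_error(primer_pair("ACGT", "ACNT"), "ACGT")
  p <- crest_primers()
  expect_equal(p$forward, "ACCAAACCGCTTCGATGTGT")
  expect_equal(p$reverse, "CGTCCCATTGGCATCACC")
})

test_that("in-silico PCR amplifies the published fragment pattern", {
  expect_equal(insilico_pcr(fixture_hapseq("crWT"))$length, 241L)
  expect_equal(insilico_pcr(fixture_hapseq("Cr1"))$length, 438L)
  expect_equal(insilico_pcr(fixture_hapseq("Cr2"))$length, 438L)
  expect_equal(insilico_pcr(fixture_hapseq("Cr3"))$length, 440L)
  # forward site alone amplifies nothing
  ref <- fixture_ref(1)
  co <- ref$coords
  tmpl <- ref_slice(ref, co$fwd_site_start - 50L, co$unit_end)
  expect_equal(nrow(insilico_pcr(tmpl)), 0L)
  # max_product cap suppresses the product
  expect_equal(nrow(insilico_pcr(fixture_hapseq("crWT"),
                                 max_product = 200L)), 0L)
})

test_that("the duplicated-template product exceeds wild type by the unit, any seed", {
  for (seed in c(2, 23)) {
    ref <- build_reference(seed)
    wt <- insilico_pcr(hap_sequence(ref, build_allele(ref, "crWT")))$length
    dup <- insilico_pcr(hap_sequence(ref, build_allele(ref, "Cr1")))$length
    expect_equal(dup - wt, 197L)
    expect_equal(wt, 241L)
  }
})

test_that("fragment interpretation follows the gel decision table", {
  expect_equal(fragment_interpret(c(438L, 241L)), "het")
  expect_equal(fragment_interpret(241L), "hom_wt")
  expect_equal(fragment_interpret(c(438L, 438L)), "hom_dup")
  expect_equal(fragment_interpret(440L, tol = 3L), "hom_dup")
  expect_equal(fragment_interpret(integer(0)), "fail")
  expect_equal(fragment_interpret(c(241L, 300L)), "fail")
  expect_equal(fragment_interpret(444L, tol = 3L), "fail")
})

test_that("the KASP model reads the 3' copy base", {
  ref <- fixture_ref(1)
  wt <- fixture_hapseq("crWT")
  bm <- fixture_hapseq("Cr2_backmutant")
  cr2 <- fixture_hapseq("Cr2")
  expect_equal(kasp_genotype(wt, wt, ref), "C/C")
  expect_equal(kasp_genotype(wt, bm, ref), "C/A")
  expect_equal(kasp_genotype(cr2, cr2, ref), "A/A")
  expect_true(is.na(kasp_genotype("ACGT", wt, ref)))
})

test_that("the diagnostic decision flow reproduces the published routing", {
  ref <- fixture_ref(1)
  wt <- fixture_hapseq("crWT")
  cr1 <- fixture_hapseq("Cr1")
  cr2 <- fixture_hapseq("Cr2")
  bm <- fixture_hapseq("Cr2_backmutant")

  polish <- diagnose_individual(cr2, cr2, ref, "polish")
  expect_equal(polish$fragments, "438")
  expect_equal(polish$final_genotype, "Cr2/Cr2")
  expect_match(polish$rule_trace, "sanger")

  amer <- diagnose_individual(wt, bm, ref, "ameraucana")
  expect_equal(amer$fragments, "241")
  expect_equal(amer$kasp_call, "C/A")
  expect_equal(amer$final_genotype, "Cr2_backmutant/crWT")

  ctrl <- diagnose_individual(wt, wt, ref, "ctrl")
  expect_equal(ctrl$fragments, "241")
  expect_equal(ctrl$kasp_call, "C/C")
  expect_equal(ctrl$final_genotype, "crWT/crWT")

  cross <- diagnose_individual(cr1, wt, ref, "cross")
  expect_equal(cross$frag_class, "het")
  expect_equal(cross$final_genotype, "Cr1/crWT")

  broken <- diagnose_individual("ACGTACGT", wt, ref, "broken")
  expect_equal(broken$final_genotype, "fail")
})

test_that("cohort diagnosis matches the generator truth with zero discordance", {
  ref <- fixture_ref(1)
  ch <- fixture_mini_cohort()
  res <- diagnose_cohort(ch, ref)
  ind <- ch$samples$sample_kind == "individual"
  truth <- vapply(which(ind), function(i) {
    haps <- ch$haplotypes[[ch$samples$sample_id[i]]]
    crestmap:::genotype_label(haps[[1]]$allele, haps[[2]]$allele)
  }, character(1))
  expect_equal(res$final_genotype, unname(truth))
})

test_that("cohort summaries conserve per-breed totals", {
  ref <- fixture_ref(1)
  ch <- fixture_mini_cohort()
  res <- diagnose_cohort(ch, ref)
  tab <- cohort_summary(res, ch$samples)
  gt_cols <- setdiff(names(tab), c("breed", "phenotype", "total"))
  expect_equal(rowSums(tab[gt_cols]), tab$total, ignore_attr = TRUE)
  ind <- ch$samples[ch$samples$sample_kind == "individual", ]
  per_breed <- table(ind$breed)
  expect_equal(tab$total, as.integer(per_breed[tab$breed]),
               ignore_attr = TRUE)
  expect_equal(sum(tab$total), nrow(ind))
  # empty input -> empty table
  expect_equal(nrow(cohort_summary(res[0, ], ch$samples)), 0L)
})
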