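mk_site <- function(geno, af, phen, kind) {
  list(geno = geno, af = af, is_case = phen != "non_crested",
       is_pool = kind == "pool")
}

test_that("site concordance follows the shared-ancestor rule", {
  phen <- c(rep("crested_large", 5), rep("non_crested", 3))
  kind <- rep("individual", 8)
  geno <- c(rep("1/1", 5), "0/1", "0/0", "1/1")
  af <- rep(NA_real_, 8)
  s <- mk_site(geno, af, phen, kind)
  res <- site_concordance(s$geno, s$af, s$is_case, s$is_pool)
  expect_true(res$concordant)
  expect_equal(res$shared_allele, "alt")

  geno2 <- geno; geno2[3] <- "0/1"   # one heterozygous case
  res2 <- site_concordance(geno2, af, s$is_case, s$is_pool)
  expect_false(res2$concordant)
  # but a carrier-based dominant model accepts it
  res3 <- site_concordance(geno2, af, s$is_case, s$is_pool,
                           mode = "dominant_carrier")
  expect_true(res3$concordant)
})

test_that("pools join concordance through the fixation threshold", {
  phen <- c(rep("crested_large", 4), "non_crested")
  kind <- c("individual", "individual", "individual", "pool", "individual")
  geno <- c("1/1", "1/1", "1/1", NA, "0/0")
  af <- c(NA, NA, NA, 0.97, NA)
  res <- site_concordance(geno, af, phen != "non_crested", kind == "pool",
                          pool_fix_threshold = 0.95)
  expect_true(res$concordant)
  af[4] <- 0.90
  res2 <- site_concordance(geno, af, phen != "non_crested", kind == "pool",
                           pool_fix_threshold = 0.95)
  expect_false(res2$concordant)
})

test_that("missing case genotypes break or pass concordance per policy", {
  phen <- c("crested_large", "crested_large", "non_crested")
  kind <- rep("individual", 3)
  geno <- c("1/1", "./.", "0/0")
  af <- rep(NA_real_, 3)
  strict <- site_concordance(geno, af, phen != "non_crested",
                             kind == "pool")
  expect_false(strict$concordant)
  perm <- site_concordance(geno, af, phen != "non_crested", kind == "pool",
                           missing_policy = "permissive")
  expect_true(perm$concordant)
  expect_error(site_concordance(geno, af, rep(FALSE, 3), kind == "pool"),
               "no case")
})

test_that("the scan matches the brute-force oracle on toy matrices", {
  set.seed(99)
  for (rep in 1:40) {
    gm <- random_toy_matrix(n_sites = sample(3:12, 1),
                            n_samples = sample(4:8, 1),
                            n_pools = sample(0:2, 1),
                            n_cases = sample(1:3, 1))
    cand <- genomic_interval("chr33", 7500000L, 7700000L)
    got <- shared_interval_scan(gm, cand)
    want <- oracle_scan(gm, cand)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_support_sites, want$n_support_sites)
    }
  }
})

test_that("a fully discordant matrix yields no intervals", {
  set.seed(7)
  gm <- random_toy_matrix(8, 6, n_pools = 0, n_cases = 2)
  case <- gm$samples$phenotype != "non_crested"
  gm$samples$sample_kind[case] <- "individual"
  gm$af[, case] <- NA_real_
  gm$geno[, which(case)[1]] <- "0/1"   # one case het everywhere
  out <- shared_interval_scan(gm, genomic_interval("chr33", 7500000L,
                                                   7700000L))
  expect_equal(nrow(out), 0L)
})

test_that("scan on the synthetic panel recovers the 1.9 kb shared interval", {
  ch <- fixture_wgs_cohort()
  iv <- shared_interval_scan(ch$matrix, crest_candidate_region())
  expect_equal(iv$start[1], 7585881L)
  expect_equal(iv$end[1], 7587784L)
  expect_equal(iv$length[1], 1904L)
  expect_equal(iv$n_support_sites[1], 6L)
  expect_false(is.na(iv$flank_discordant_left[1]))
  # BED export is 0-based half-open
  p <- withr::local_tempfile(fileext = ".bed")
  write_ibd_bed(iv, "chr33", p)
  f <- strsplit(readLines(p)[1], "\t")[[1]]
  expect_equal(as.integer(f[2:3]), c(7585880L, 7587784L))
})

test_that("the concordance filter keeps exactly the fully concordant variants", {
  ch <- fixture_wgs_cohort()
  top <- genomic_interval("chr33", 7585881L, 7587784L)
  cand <- concordance_filter(ch$matrix, top)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$vtype, "DUP")
  expect_equal(cand$case_carrier_fraction, 1)
  expect_equal(cand$control_carrier_fraction, 0)

  # a variant carried by a single control is excluded
  gm <- ch$matrix
  ctrl <- which(gm$samples$phenotype == "non_crested" &
                  gm$samples$sample_kind == "individual")
  dup_row <- which(gm$variants$vtype == "DUP")
  gm$geno[dup_row, ctrl[1]] <- "0/1"
  expect_equal(nrow(concordance_filter(gm, top)), 0L)

  # a variant carried by everyone is excluded too
  gm2 <- ch$matrix
  gm2$geno[dup_row, !is.na(gm2$geno[dup_row, ])] <- "1/1"
  gm2$af[dup_row, gm2$samples$sample_kind == "pool"] <- 1
  expect_equal(nrow(concordance_filter(gm2, top)), 0L)
})

test_that("candidates are supported sites and controls only shrink the list", {
  ch <- fixture_mini_cohort()
  iv <- shared_interval_scan(ch$matrix, crest_candidate_region())
  top <- genomic_interval("chr33", iv$start[1], iv$end[1])
  cand <- concordance_filter(ch$matrix, top)
  expect_true(all(cand$pos >= top$start & cand$pos <= top$end))

  gm <- ch$matrix
  set.seed(31)
  for (rep in 1:5) {
    # append a control with random genotypes
    n <- nrow(gm$variants)
    new_geno <- cbind(gm$geno, sample(c("0/0", "0/1", "1/1"), n, TRUE))
    new_af <- cbind(gm$af, rep(NA_real_, n))
    new_sheet <- rbind(gm$samples, data.frame(
      sample_id = sprintf("extra_%d", rep), breed = "x",
      phenotype = "non_crested", sample_kind = "individual"))
    gm <- genotype_matrix(gm$variants, new_sheet, new_geno, new_af)
    shrunk <- concordance_filter(gm, top)
    expect_lte(nrow(shrunk), nrow(cand))
    expect_true(all(shrunk$id %in% cand$id))
    cand <- shrunk
  }
})
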