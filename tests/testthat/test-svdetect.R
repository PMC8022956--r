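sv_region <- function() genomic_interval("chr33", 7578000L, 7598000L)

test_that("wild-type samples give no junctions, everted clusters or calls", {
  ref <- fixture_ref(1)
  hw <- build_allele(ref, "crWT")
  for (seed in c(1, 2, 3)) {
    aln <- simulate_alignments(ref, list(hw, hw), coverage = 20,
                               region = sv_region(), seed = seed)
    ev <- collect_evidence(aln, sv_region())
    expect_equal(nrow(ev$junctions), 0L)
    expect_equal(nrow(ev$everted), 0L)
    expect_equal(nrow(call_tandem_dup(ev, ref)), 0L)
  }
})

test_that("homozygous duplication yields the exact split junction and call", {
  ref <- fixture_ref(1)
  h1 <- build_allele(ref, "Cr1")
  aln <- simulate_alignments(ref, list(h1, h1), coverage = 20,
                             region = sv_region(), seed = 1)
  ev <- collect_evidence(aln, sv_region())
  expect_equal(ev$junctions$donor_end[1], 7587784L)
  expect_equal(ev$junctions$acceptor_start[1], 7587588L)

  # split-read count against the binomial expectation
  span <- 20000L + 197L
  n_frag <- round(5 * span / 100)          # per haplotype
  p <- 71 / (span - 99)                    # both anchors >= 15 bp
  m <- 2 * 2 * n_frag * p
  expect_lt(abs(sum(ev$junctions$support) - m), 3 * sqrt(m) + 1)

  calls <- call_tandem_dup(ev, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$unit_length, 197L)
  expect_equal(calls$start, 7587588L)
  expect_equal(calls$end, 7587784L)
  expect_equal(calls$genotype, "hom")
  expect_gte(calls$sr_support + calls$pe_support, 3)
})

test_that("short-insert fragments straddling the junction look everted", {
  ref <- fixture_ref(1)
  h1 <- build_allele(ref, "Cr1")
  aln <- simulate_alignments(ref, list(h1, h1), coverage = 40,
                             frag_mean = 250, frag_sd = 15,
                             region = sv_region(), seed = 4)
  ev <- collect_evidence(aln, sv_region())
  expect_gt(nrow(ev$everted), 0L)
  expect_true(any(ev$everted$lo <= 7587784L & ev$everted$hi >= 7587588L))
})

test_that("a lone discordant pair does not form a cluster", {
  ref <- fixture_ref(1)
  aln <- data.frame(
    qname = c("f1", "f1"), flag = c(81L, 161L), rname = "chr33",
    pos = c(7587600L, 7587750L), mapq = 60L, cigar = "100M",
    rnext = "=", pnext = c(7587750L, 7587600L), tlen = c(250L, -250L),
    seq = strrep("A", 100), qual = strrep("I", 100), sa = NA_character_,
    stringsAsFactors = FALSE)
  ev <- collect_evidence(aln, sv_region(), min_cluster = 2L)
  expect_equal(nrow(ev$everted), 0L)
})

test_that("heterozygotes are genotyped from a depth ratio near 1.5", {
  ref <- fixture_ref(1)
  h1 <- build_allele(ref, "Cr1")
  hw <- build_allele(ref, "crWT")
  # the ratio over a 197 bp window is noisy at a single draw; its mean over
  # seeds settles at the copy-number expectation
  ratios <- vapply(1:5, function(seed) {
    aln <- simulate_alignments(ref, list(h1, hw), coverage = 30,
                               region = sv_region(), seed = seed)
    ev <- collect_evidence(aln, sv_region())
    calls <- call_tandem_dup(ev, ref)
    expect_equal(calls$genotype[1], "het")
    calls$depth_ratio[1]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1.5), 0.15)
})

test_that("depth ratios behave as copy-number arithmetic predicts", {
  # uniform profile -> exactly 1
  unit <- genomic_interval("chr33", 7587588L, 7587784L)
  flat <- rep(10L, 20001L)
  expect_equal(depth_ratio(flat, 7578000L, unit), 1.0)
  expect_error(depth_ratio(rep(0L, 20001L), 7578000L, unit), "zero flank")

  ref <- fixture_ref(1)
  h1 <- build_allele(ref, "Cr1")
  hw <- build_allele(ref, "crWT")
  genos <- list(wt = list(hw, hw), het = list(h1, hw), hom = list(h1, h1))
  want <- c(wt = 1.0, het = 1.5, hom = 2.0)
  tol <- c(wt = 0.15, het = 0.15, hom = 0.3)
  for (g in names(genos)) {
    aln <- simulate_alignments(ref, genos[[g]], coverage = 40,
                               region = sv_region(), seed = 8)
    ev <- collect_evidence(aln, sv_region())
    dr <- depth_ratio(ev$depth, ev$depth_start, unit)
    expect_lt(abs(dr - want[[g]]), tol[[g]])
  }
})

test_that("breakpoints left-align through planted microhomology", {
  # toy reference: unit [31, 50], with the 4 bases before the unit equal to
  # the unit's last 4 bases -> 4 bp of junction microhomology
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  substr(s, 27, 30) <- "TACG"
  substr(s, 47, 50) <- "TACG"
  toy <- structure(list(
    region = genomic_interval("chrT", 1L, 80L), sequence = s),
    class = "crest_reference")
  want <- crestmap:::left_align_junction(toy, 50L, 31L)
  for (shift in 0:4) {
    got <- crestmap:::left_align_junction(toy, 50L - shift, 31L - shift)
    expect_equal(got, want)
  }
  expect_equal(unname(want["donor_end"] - want["acceptor_start"]),
               unname(50L - 31L))  # unit length preserved
})

test_that("breakpoint recovery is exact across seeds at 20x", {
  ref <- fixture_ref(1)
  h1 <- build_allele(ref, "Cr1")
  hits <- 0L
  seeds <- 1:10
  for (seed in seeds) {
    aln <- simulate_alignments(ref, list(h1, h1), coverage = 20,
                               region = sv_region(), seed = seed)
    calls <- call_tandem_dup(collect_evidence(aln, sv_region()), ref)
    if (nrow(calls) == 1L && calls$start == 7587588L &&
        calls$end == 7587784L) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / length(seeds), 0.95)
})
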