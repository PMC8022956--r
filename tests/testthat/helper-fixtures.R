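# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_ref <- function(seed = 1L) {
  cached(paste0("ref_", seed), build_reference(seed))
}

# scaled-down WGS-style panel: enough cases/controls/pools for the scan
# logic, small enough for fast unit tests
mini_panel_design <- function(n_controls = 24L) {
  g <- function(breed, phen, a, b, n, kind = "individual",
                pool = NA_integer_)
    data.frame(breed = breed, phenotype = phen, allele_a = a, allele_b = b,
               n = n, sample_kind = kind, pool_size = pool,
               stringsAsFactors = FALSE)
  d <- rbind(
    g("Silkie", "crested_small", "Cr1", "Cr1", 3L),
    g("Polish", "crested_large", "Cr2", "Cr2", 2L),
    g("Dutch-Polish", "crested_large", "Cr3", "Cr3", 1L),
    g("Silkie", "crested_small", "Cr1", "Cr1", 1L, "pool", 10L),
    g("Other breeds", "non_crested", "crWT", "crWT", n_controls))
  crestmap:::new_design(d, bg_sites = 60L)
}

fixture_mini_cohort <- function() {
  cached("mini_cohort", generate_cohort(fixture_ref(1L),
                                        mini_panel_design(), seed = 1L))
}

fixture_wgs_cohort <- function() {
  cached("wgs_cohort", generate_cohort(fixture_ref(1L),
                                       wgs_panel_design(), seed = 1L))
}

fixture_hapseq <- function(allele, seed = 1L) {
  cached(paste0("hapseq_", allele, "_", seed), {
    ref <- fixture_ref(seed)
    hap_sequence(ref, build_allele(ref, allele))
  })
}

# Random toy genotype matrix for oracle comparisons.
random_toy_matrix <- function(n_sites, n_samples, n_pools = 1L,
                              n_cases = 2L) {
  pos <- sort(sample.int(100000L, n_sites)) + 7500000L
  variants <- data.frame(
    chrom = "chr33", pos = pos, id = sprintf("v%d", seq_len(n_sites)),
    ref = "A", alt = "G", vtype = "SNV", end = NA_integer_,
    stringsAsFactors = FALSE)
  kind <- c(rep("pool", n_pools), rep("individual", n_samples - n_pools))
  phen <- sample(c(rep("crested_large", n_cases),
                   rep("non_crested", n_samples - n_cases)))
  sheet <- data.frame(
    sample_id = sprintf("s%d", seq_len(n_samples)), breed = "toy",
    phenotype = phen, sample_kind = sample(kind),
    stringsAsFactors = FALSE)
  is_pool <- sheet$sample_kind == "pool"
  geno <- matrix(NA_character_, n_sites, n_samples)
  af <- matrix(NA_real_, n_sites, n_samples)
  geno[, !is_pool] <- sample(c("0/0", "0/1", "1/1", "./."),
                             n_sites * sum(!is_pool), replace = TRUE,
                             prob = c(0.4, 0.25, 0.3, 0.05))
  af[, is_pool] <- round(stats::runif(n_sites * sum(is_pool)), 2)
  genotype_matrix(variants, sheet, geno, af)
}

# Independent brute-force scan oracle: tests every contiguous site run for
# homozygous sharing, by direct genotype comparison.
oracle_scan <- function(gm, candidate, thr = 0.95) {
  v <- gm$variants
  keep <- which(v$pos >= candidate$start & v$pos <= candidate$end)
  case <- gm$samples$phenotype != "non_crested"
  pool <- gm$samples$sample_kind == "pool"
  conc <- vapply(keep, function(j) {
    g <- gm$geno[j, case & !pool]
    a <- gm$af[j, case & pool]
    (all(g == "1/1") && all(a >= thr)) ||
      (all(g == "0/0") && all(a <= 1 - thr))
  }, logical(1))
  n <- length(keep)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(conc[i:j]) && (i == 1L || !conc[i - 1L]) &&
          (j == n || !conc[j + 1L])) {
        rp <- crestmap:::variant_right_pos(v[keep[i:j], , drop = FALSE])
        out <- rbind(out, data.frame(start = v$pos[keep[i]],
                                     end = max(rp),
                                     n_support_sites = j - i + 1L))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      n_support_sites = integer(0))
  }
  out[order(-(out$end - out$start + 1L)), , drop = FALSE]
}
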