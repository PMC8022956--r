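---
title: "Methods: synthetic fine-mapping of the chicken Crest locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic fine-mapping of the chicken Crest locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

The *Crest* mutation replaces the small feathers of the chicken head with
large dorsal-type feathers. Its causal mutation is a 197 bp tandem
duplication of a conserved sequence in the intron of *HOXC10*
(Chr33:7,587,588–7,587,784 on GalGal6), found by scanning a 250 kb
candidate region (7.57–7.82 Mb of chromosome 33) for segments identical by
descent (IBD) across crested birds of many breeds, then keeping the one
variant fully concordant with phenotype. crestmap rebuilds that pipeline on
synthetic data, so every coordinate-level claim is checkable without the
original sequencing panel.

The genetic model distinguishes five haplotypes at the locus:

| allele | structure | copy-specific edit |
|---|---|---|
| `crWT` | single copy | none (C at 7,587,629; (TG)₇ at 7,587,694) |
| `Cr1` | tandem duplication | none |
| `Cr2` | tandem duplication | C→A at unit offset 42 in the 3′ copy |
| `Cr3` | tandem duplication | (TG)₇→(TG)₈ at unit offset 107 in the 5′ copy |
| `Cr2_backmutant` | single copy | carries the A base (loss of one *Cr2* copy) |

The unit-internal offsets (42 and 107) are derived once from the genomic
anchors (7,587,629 − 7,587,588 + 1 and 7,587,694 − 7,587,588 + 1) and
asserted against the reference model in the tests.

## The synthetic reference

`build_reference(seed)` draws a uniform random nucleotide sequence for
chr33:7,500,000–7,820,000 and plants only the features the analyses rely
on: the 197 bp unit with its C base and perfect (TG)₇ run, and the two
diagnostic primer sites. Design choices:

* **Real sequence is not used.** Only the coordinates are preserved. This
  keeps the artifact self-contained; the cost is that sequence-context
  effects (GC bias, mappability, repeat content) are absent.
* **Primer spacing is calibrated to the wild-type amplicon.** The forward
  primer ends 3 bp before the unit and the reverse-complement site ends
  22 bp after it, making the single-copy product exactly 241 bp. The
  duplication-template product is then an emergent prediction
  (241 + 197 = 438 bp; 440 bp for *Cr3*), not a hard-coded constant.
* **Scrubbing.** After planting, any other exact occurrence of either
  primer (both strands, whole region) and any other (TG)₆₊ run within 5 kb
  of the unit is destroyed by a deterministic single-base edit, so primer
  matching and microsatellite typing are unambiguous. The base before the
  unit is forced to differ from the unit's last base, giving the planted
  junction zero microhomology; breakpoint left-alignment is therefore
  exact on this reference, and the microhomology code path is exercised
  separately on toy sequences.

## The cohort generator

`generate_cohort()` is the stand-in for the study's whole-genome panel.
The default `wgs_panel_design()` mirrors its composition: 22 crested
samples (18 individuals plus 4 pools of 10 birds) homozygous for
duplication alleles — breeds with small crests carry *Cr1*, breeds with
large or upward crests carry *Cr2*/*Cr3* — and 197 non-crested wild-type
individuals. `table1_design()` reproduces the published per-breed
diagnostic cohort (54 crested plus 433 non-crested birds). Crested panel
samples default to homozygous because the crested purebreds are reported
fixed for their alleles; heterozygote rows can be added to a design
explicitly.

The variant structure encodes the logic the scan must rediscover:

* all duplication-bearing (and back-mutant) haplotypes carry the four
  linked SNVs at 7,586,870 / 7,586,999 / 7,587,089 / 7,587,313;
* a minority of wild-type haplotypes (default 5%, forced to at least one
  carrier whenever wild-type haplotypes exist) also carries them — so the
  SNVs are shared by every case yet fail the concordance filter, leaving
  the duplication as the single fully concordant variant;
* the 5′ IBD boundary at 7,585,881 is modelled as a marker where all case
  haplotypes carry the *reference* allele while controls segregate. The
  published interval start prints no case-specific variant, so this is a
  modelling decision, chosen because it reproduces both the printed
  1.9 kb interval and the count of five in-interval sequence changes
  without contradiction. The 3′ boundary coincides with the duplication
  end, reported through the DUP record's END coordinate;
* the polymorphic sites immediately flanking the interval are forced
  case-discordant (one case individual is made heterozygous), so the
  scan's boundaries do not drift with sampling noise;
* background SNVs (default 160 sites, population frequencies uniform on
  0.1–0.9) are placed outside a 7,585,500–7,588,000 exclusion window. The
  locus itself is kept free of incidental variation — consistent with its
  conservation — which also guarantees the diagnostic primers always match
  exactly.

Pools are genotyped as alt-allele frequencies (a dedicated `AF` FORMAT
field in the truth VCF), individuals as diploid `GT`. Pool handling in the
scan uses fixation thresholds (fixed ≥ 0.95, absent = 0); the original
study does not describe its pool treatment, so the thresholds are exposed
as parameters.

## Read simulation

`simulate_alignments()` draws fragments (default length 350 ± 50 bp, reads
2 × 100 bp, total depth 20×, error-free) uniformly along each haplotype
and places every read on the reference *analytically* from the haplotype's
block coordinate map — no aligner runs. Reads spanning the
duplication junction become primary + supplementary split alignments with
exact clip lengths (supplementary segments shorter than 15 aligned bases
are left soft-clipped, as an aligner could not anchor them); fragments
whose inner span is shorter than the unit produce the everted
(reverse-before-forward) pair orientation. With the default 350 bp insert
the inner span usually exceeds 197 bp, so split reads — not everted pairs —
carry most of the signal, which matches the genotype of evidence the
detector weighs. Uniform substitution errors are available but default to
0; indel errors and quality modelling are out of scope.

## Detection, classification, diagnostics

The SV caller takes breakpoints from the modal split-read junction,
left-aligns them through any microhomology (the VCF convention), and
genotypes from the unit/flank depth ratio with boundaries 1.25 and 1.75
(heterozygous in between, homozygous above; below 1.25 the fraction of
junction-spanning reads breaks the tie at 0.7). `min_support` defaults
to 3 combined split + everted observations, a conventional small-cohort
threshold. Depth ratios over a 197 bp window are noisy at 20–30×
(coefficient of variation near 10%), which is why genotype boundaries are
wide and the tests check ratio expectations on averages across seeds.

The classifier locates the unit between two unique 30 bp flank anchors and
tolerates up to 3 edits per copy (the modelled allele edits are 1–2 bp);
the 5′/3′ copy identity is positional. The diagnostic assay mirrors the
published decision flow: exact-match in-silico PCR (primer mismatch
tolerance is deliberately 0 — the primers are given and the templates
synthetic), gel interpretation with ±3 bp tolerance (so the 440 bp *Cr3*
product reads as a duplication fragment), Sanger-style per-haplotype
classification for duplication carriers, and a KASP-style direct base call
at 7,587,629 for the rest, reading the 3′ copy in duplicated haplotypes.
Heterozygous 438/241 samples are resolved per haplotype, the computational
analogue of sequencing the 438 bp product. The two Ameraucana back-mutant
heterozygotes are not part of the per-breed table (the published table
counts its 433 non-crested birds as wild-type homozygotes); the back-mutant
route is exercised separately.

ΔΔCt uses amplification efficiency fixed at 2 (the normalisation is stated
in the source without a formula); any consistent calibrator sample gives
calibrator fold 1 by construction, and raw Ct inputs are synthetic because
the study's raw Cts are unpublished — the expression module demonstrates
behaviour, it does not reproduce published fold values.

## Problem sizes, determinism, degenerate inputs

Simulations in the tests and the acceptance script run at the study-like
conditions (20× depth, the full 219-sample panel, the 487-bird diagnostic
cohort) but restrict read simulation to windows of 20–250 kb around the
locus, which leaves every measured quantity unchanged while keeping runs
to seconds or minutes. All randomness flows from explicit integer seeds
(`withr::with_seed`), so every pipeline stage is reproducible bit for bit;
the pipeline manifest differs between identical runs only in its
timestamp. Degenerate inputs are defined: empty designs yield empty
matrices, a cohort without cases fails the scan with a named stage error,
coverage ≤ 0 and zero flank depth are errors, designs requesting crested
back-mutant homozygotes are rejected as biologically contradictory, and
sequences without both flank anchors classify as `unknown` rather than
crash the diploid path.

## What passing tests do and do not show

The generator emulates haplotype structure, pooling, read-pair geometry
and depth — not alignment artefacts, repeat-induced mismapping, sequencing
error profiles, population structure within breeds, or recombination
inside the candidate region. Recovery of the published coordinates here
demonstrates that the algorithms implement the discovery logic correctly;
it does not re-establish the biological result, which rests on the
original sequencing data.
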