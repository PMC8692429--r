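---
title: "Methods and design of vitipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of vitipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`vitipop` implements the windowed population-genomic toolchain used to
dissect domestication history in clonally propagated crops such as
grapevine: genotype-call filtering keyed to per-sample modal coverage,
windowed identity-by-descent (IBD) kinship classification, outgroup
polarization and site-frequency analysis, ABBA–BABA/f_d introgression scans,
diversity and selective-sweep scans, regional haplotype inference, and
allele-specific expression (ASE) meta-analysis. This vignette explains the
models, the tunable parameters and their defaults, the synthetic cohort
generator that the test suite is built on, and the design decisions taken
where the published procedures leave room.

## 1. Data model and windows

A cohort is a `genotype_dataset`: biallelic SNPs (strictly increasing 1-based
positions per chromosome) by samples, with alternate-allele dosage genotypes,
optional per-call DP/AD/PL, per-site QUAL, a repeat-mask flag, and an
optional phasing that is kept consistent with the genotypes (phase is set to
`NA` wherever a call is uncertain). Invariants are enforced on construction:
`AD_ref + AD_alt <= DP` and exactly one PL of 0 per called genotype; data
violating them are rejected rather than repaired.

All coordinates are 0-based half-open internally (mask intervals, windows);
conversion to and from 1-based VCF positions and BED happens only at the I/O
boundary. Two windowing schemes cover every scan:

* `nonrep_fixed` — greedy left-to-right accumulation of unmasked bases;
  a window closes at the base where the running total reaches `w` (default
  100 kb of non-repetitive DNA), so windows have constant information
  content and variable physical span. The trailing remainder of each
  chromosome becomes a short window flagged `partial`, excluded from scans
  by default: the published procedure uses "variable size" windows but does
  not say what happens to the remainder, and mixing a sub-sized window into
  per-window statistics would bias them. A masked run spanning a window
  boundary simply continues the accumulation — closure happens exactly at
  the `w`-th unmasked base.
* `sliding` — fixed span and step (defaults 100 kb / 25 kb), each window
  annotated with its non-repetitive content.

## 2. The filter cascade

The call-retention rules (quality > 50, depth ≥ 5, a modal-coverage band,
allele balance, homozygous-PL rules, per-allele depth fraction) and the
site-retention rules (> 50% of samples passing, ≥ 1 passing carrier, outside
repeats) are applied as a deterministic two-pass algorithm: pass 1 evaluates
every rule with the strict coverage band; pass 2 re-admits calls that failed
*only* the upper bound, lie within 2.5× modal coverage, and sit at sites
where at least five other samples passed pass 1. The published rule does not
specify evaluation order; two passes with strict-pass supporters avoid any
fixed-point ambiguity. "AD/DP > 0.05" is applied to every *called* allele
(both alleles of a heterozygote), the conservative reading. QUAL is the
site-level VCF value, since standard VCF has no per-sample variant quality.

Modal coverage — the mode of a sample's integer DP histogram, ties broken
toward the smaller depth — is estimated once from the unfiltered call set
and travels with the filtered dataset (attribute `modal_coverage`). This is
deliberate: at Poisson-distributed depth with integer mean the histogram
mode is a coin flip between two adjacent values (e.g. P(25) = P(26) exactly
when the mean is 26), so re-estimating it on filtered output would make the
cascade non-idempotent for no scientific reason. With the stored estimate,
running the cascade on its own output changes nothing, and the test suite
asserts this.

## 3. Windowed IBD and relationship classification

For each sample pair and window the profile records the fraction of
informative sites (both called) that are opposite homozygotes, identical,
and the mean absolute dosage difference / 2 (genotypic distance); the
identity-by-state ratio is the complement of the opposite-homozygote
fraction. The window state is IBD = 0 if opposite homozygotes exceed
`t0 = 0.02`; else IBD = 2 if identical genotypes exceed `t2 = 0.95` and
genotypic distance is below `d2 = 0.03`; else IBD = 1. Windows with fewer
than 10 informative sites stay unclassified. These per-window statistics are
operational stand-ins for the per-window statistics used in the literature;
alternative formulations exist in the literature, so they are isolated
behind `ibd_thresholds()` and can be swapped without touching the
classifier.

Segments are maximal runs of equal state over classified windows per
chromosome, with length the physical span (Mb) of their constituent windows.
Percentages (pct0/1/2) are of classified physical length, not window count.
The classifier is the reference decision list, evaluated clone → PO → FS →
HS → `gt2nd`, first match wins, with every comparison recorded in a trace.
Paired upper/lower bounds are read as between-bounds (e.g. IBD = 0 content
between 10% and 20% for full sibs). With fewer than two segments a dispersion statistic
is defined as 0 (this makes error-free PO pairs, which have no IBD = 0
segments at all, satisfy the sd < 0.1 Mb bound).

**A structural caveat.** The reference thresholds encode the empirical texture
of the pipeline they were derived with, and two of them cannot be satisfied
by a truth-faithful simulation no matter how its parameters are chosen:

* the clone rule requires IBD1 > 3% of the genome, which an error-free clone
  pair (pct1 = 0) can never meet — `relationship_rules(clone_ibd1_min = 0)`
  is the documented alternative;
* the FS rule requires the standard deviation of IBD = 0 segment lengths to
  be below 0.2 Mb while that of IBD = 2 segments exceeds 0.23 Mb, yet for
  full sibs the IBD = 0 and IBD = 2 segment-length processes are
  exchangeable by construction (each is the intersection of the same two
  two-state recombination processes at stationary frequency 1/4), and the
  10–20% band for IBD = 0 content excludes the Mendelian expectation
  of 25%.

The package therefore classifies error-free PO and unrelated pairs reliably,
while simulated FS pairs fall through to HS/`gt2nd` and clone recovery
depends on the genotyping-error rate; the recovery rates actually measured
are reported by `scripts/acceptance.R` rather than asserted here. Users
analysing real data, whose window-state calls carry the same kind of noise
the original thresholds were fitted to, should treat the FS/HS boundary as
data-set specific and recalibrate via `ibd_thresholds()` if needed.

## 4. Polarization and introgression scans

The ancestral allele at a site is the single allele carried by the outgroup;
sites with a heterozygous, segregating or uncalled outgroup are
non-polarizable and excluded from polarized analyses. Site patterns are
frequency-based (groups contain many samples): `ABBA = (1−p1) p2 p3 (1−pO)`
and `BABA = p1 (1−p2) p3 (1−pO)` with the outgroup term retained for
robustness to residual outgroup polymorphism. `D` sums pattern differences
over a window; the genome-wide `D` carries a delete-one block jackknife over
blocks of 300 consecutive informative SNPs (blocking by SNP count, not
physical length). The admixture-fraction estimator `f_d` replaces the donor
slot of the denominator, site by site, with whichever of P2/P3 has the
higher derived frequency; windows with `D ≤ 0` report `f_d` as undefined
(a `fd_zero` flag emits 0 instead for plotting). The windowed topology scan
reduces per-window trees to the criterion actually used to flag windows:
Nei's `D_A` between the focal group and each comparison group, flagging
windows where the focal group is nearest to the donor; an f3 test
(`mean (pT−pA)(pT−pB)` with block jackknife) is provided for corroborating
admixture signals.

`f_d` is accurate only when the donor population carries many strongly
differentiated alleles relative to the sister pair: the `max(p2, p3)`
denominator is inflated by sampling and drift noise whenever the two
frequencies are comparable, attenuating the estimate. This is a property of
the estimator, and it drove the simulator's default drift depths (below).

## 5. Diversity, sweeps, ROH, regional haplotypes

Both diversity estimators are unbiased (`n/(n−1)` corrected): windowed π
uses per-site called-haplotype counts (missing calls reduce `n` site-wise)
divided by the window's non-repetitive length; haplotype diversity is
computed in non-overlapping blocks of five consecutive variant sites within
a chromosome, summarized as non-overlapping means of 50 blocks, and smoothed
with a cubic smoothing spline whose penalty is chosen by generalized
cross-validation unless `spar` is given. Blocks never span chromosome ends;
trailing partial blocks and point groups are dropped. Sweep calls are runs
of plotted points whose smoothed value falls below the genome-wide 5%
quantile (strict), merged across gaps of at most 2 points, each reporting
the nadir. Runs of homozygosity are maximal runs of called sites with at
most one heterozygote, at least 50 sites and 100 kb; these three parameters
are package defaults — the analysis they support does not prescribe any.

Regional haplotype inference starts from a reference haplotype and from
accessions homozygous across the region, then iterates: an unresolved
accession is assigned when subtracting exactly one distinct panel haplotype
yields a site-wise consistent complement (identical unordered pairs are
deduplicated first — a haplotype and its complement describe the same
diplotype). Accessions with zero or several consistent resolutions stay
unresolved: the procedure never guesses, which mirrors the partial
resolution that regional panels typically achieve. Frequencies are over
resolved accessions and a diplotype frequency table is emitted.

## 6. Allele-specific expression

Each replicate's allele-resolved counts are tested with a two-sided exact
binomial test against the null ratio 0.5 — a transparent substitute for the
original tool-internal likelihood statistic — converted to a signed z, and
combined as `Z = Σ w_i z_i / sqrt(Σ w_i²)`. The weights are configurable and
default to the square root of replicate depth, since the original analysis
specifies "with weight" without defining one. No multiple-testing correction
is applied by default (a BH option exists) and the significance threshold is
p < 0.05. The exact binomial's discreteness makes the combined test slightly
conservative at finite depth, so the realized type-I rate sits just below
the nominal level. FPKM is apportioned as `fpkm·r` and `fpkm·(1−r)`; the two
always sum to the total.

## 7. The synthetic cohort generator

`sim_config()` fixes the study conditions every stochastic test runs under:
12 chromosomes of 20 Mb (a grapevine-scale genome, scaled down), ~1.4×10⁻⁴
segregating sites per bp (≈ 20,000 unmasked sites genome-wide), founder
allele frequencies Beta(0.5, 0.5) truncated to [0.02, 0.98] in linkage
equilibrium, 1.5 crossovers per chromosome per meiosis, 40% of the genome
masked in ~50 kb fragments (grapevine is roughly 40% repetitive), modal
coverage 26× (Poisson per call, floored at one read), and a per-call
genotyping error of 0.002 — the order of post-filter discordance in
re-sequenced clonal material, including somatic variation between clones.
Offspring are built by meiosis with Poisson crossovers and uniform
breakpoints; clones copy genotypes before the error layer; DP/AD/PL are
drawn consistently with each observed call (PL is 0 at the call and
`10 · mismatches · DP/2` capped at 255 elsewhere — simple and monotone in
depth). Everything is recorded in a `truth_set`.

The four-taxon generator drifts population frequencies along
(((P1,P2),P3),O) with truncated Normal steps; defaults are tip drift 0.02,
split drift 0.05, donor drift 0.6, and an outgroup near-fixed for the
ancestral allele (derived frequency 0.01). The large donor drift is the
point, not an accident: pattern-based admixture estimation presupposes a
donor rich in strongly differentiated (often fixed) alleles, and with
truncated Gaussian drift that regime requires a large step. Gene flow
resamples a fraction `f` of test-population haplotypes from donor
frequencies inside tracts (whole-genome by default, explicit intervals for
localized scenarios). Sweeps are imposed, not evolved: inside a region each
target haplotype is replaced by one fixed haplotype with probability
`swept_freq ∈ (0.5, 1]`.

What the generator deliberately does *not* emulate: linkage disequilibrium
among founders (no ancestral recombination graph — IBD segment structure
comes from the pedigree meioses only, which is what the kinship classifier
consumes), coalescent site-frequency spectra (drift is Gaussian, not
genealogical; under drift alone E[D] = 0, which is exactly the null the
introgression tests need), selection dynamics, and read-level artifacts
(mapping bias, index hopping). Green tests therefore demonstrate algorithmic
correctness and statistical calibration under these conditions, not
robustness to every property of real resequencing data.

## 8. Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use: the full 12 × 20 Mb genome
with ~20,000 retained sites and 10 pairs per relationship class for kinship
recovery; two-chromosome, 50,000-site four-taxon panels (15 samples per
population, 4 outgroup) for D/f_d and D_A; ten replicate single-chromosome
sweep simulations (20,000 sites, 20 founders, swept frequency 0.95); and
500-gene, 2-replicate, depth-200 ASE panels. These sizes keep the whole
suite within a few minutes on one core while leaving each statistic's
sampling error well inside the asserted tolerances.

Numerical conventions: window π and H are exact sums (no floating-point
shortcuts are taken that could break the brute-force oracle equality
asserted in the tests); jackknife SEs use the standard delete-one-block
formula `sqrt((B−1)/B · Σ(θ_i − θ̄)²)`; degenerate cases are explicit
(windows with no informative pattern have undefined `D`, not 0; a single
jackknife block yields `NA` SE; dispersion of fewer than two segments is 0;
zero-total ASE replicates are dropped and fully-empty genes flagged
undefined rather than imputed).

## 9. Known limitations

* The per-window IBD statistics are operational stand-ins; they preserve the
  reference classification contract but not necessarily the noise behaviour
  of the estimators the thresholds were calibrated with (see §3).
* Haplotype-diversity scans require phased input; the simulator provides
  truth phase, real data needs external phasing.
* The ASE per-replicate statistic is an exact binomial, not the original
  aligner-likelihood statistic; weights and the null ratio are exposed.
* `f_d` attenuates under weak donor divergence (§4); interpret genome-wide
  `f_d` as a lower bound when the donor is poorly differentiated.
* The repeat-mask generator draws exponential fragment lengths; real repeat
  landscapes are clustered (pericentromeric), which mainly affects the
  spread of physical window spans.
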