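# vitipop

Population genomics of grapevine domestication cohorts, in R.

Cultivated grapevine (*Vitis vinifera* subsp. *sativa*) and its wild
progenitor (subsp. *sylvestris*) form a tangle of clones, pedigrees, feral
escapees and wild–cultivated hybrids. Resolving that tangle from whole-genome
resequencing takes a specific chain of windowed analyses: a multi-rule
genotype-call filter, identity-by-descent (IBD) profiling of sample pairs,
outgroup polarization, ABBA–BABA introgression scans, diversity scans for
selective sweeps, regional haplotype inference, and allele-specific
expression (ASE) tests. `vitipop` implements that chain as composable,
tibble-returning functions, together with a pedigree-aware diploid cohort
simulator with full ground truth, so every stage can be validated end to end
without any sequencing data.

The package is for population geneticists and breeders analysing diploid SNP
cohorts (grapevine or any clonally propagated perennial), and for method
developers who need a transparent, testable reference implementation of
these scans.

## The statistics at the core

* **Filter cascade** — a call passes iff QUAL > 50, DP ≥ 5, DP within
  [0.5, 1.5]× the sample's modal coverage (homozygotes: lower bound 0.25×;
  upper bound relaxed to 2.5× when ≥ 5 other samples pass at the site),
  heterozygous allele balance within [0.25, 0.75], homozygous PL = 0 with
  min non-zero PL > 10, and AD/DP > 0.05 per called allele; a site is kept
  iff unmasked, passing in > 50% of samples, with ≥ 1 passing carrier.
* **Windowed IBD** — in windows holding a fixed amount of non-repetitive DNA
  (default 100 kb), a pair is IBD = 0 where opposite homozygotes exceed 2%,
  IBD = 2 where > 95% of genotypes are identical with genotypic distance
  < 0.03, else IBD = 1. Aggregate lengths and segment-length dispersions
  feed a reference decision list for clone / parent–offspring (PO) / full-sib
  (FS) / half-sib (HS) calls; haplotypic distance is
  `(L0 + L1/2) / (L0 + L1 + L2)`.
* **Introgression** — with per-group derived-allele frequencies `p1, p2, p3,
  pO` (recipient-sister, test, donor, outgroup),
  `ABBA = (1−p1) p2 p3 (1−pO)`, `BABA = p1 (1−p2) p3 (1−pO)`,
  `D = Σ(ABBA−BABA)/Σ(ABBA+BABA)` with a 300-SNP block jackknife, and the
  admixture fraction `f_d` divides the numerator by its value with the donor
  slot set site-wise to `max(p2, p3)` (undefined where window `D ≤ 0`).
  A three-population test `f3 = mean (pT−pA)(pT−pB)` and a windowed Nei
  `D_A` topology scan complete the module.
* **Diversity** — unbiased `π = Σ [n/(n−1)] 2p(1−p) / nonrepetitive bp`;
  haplotype diversity `H = [n/(n−1)](1 − Σ p_k²)` in blocks of 5 variant
  sites, plotted as means of 50 blocks with a cubic smoothing spline; sweep
  valleys are runs of points below the genome-wide 5% quantile of the
  smoothed curve. Runs of homozygosity and iterative regional haplotype
  inference (subtract known haplotypes, never guess) round out the module.
* **ASE** — per replicate an exact binomial test against a 0.5 null,
  converted to a signed z and combined across replicates with a weighted
  Stouffer meta-analysis (`w = √depth`); gene FPKM is apportioned between
  alleles by the imbalance ratio.

## Worked example

Simulate a tiny named pedigree, filter it, and ask who is related to whom:

```r
library(vitipop)
library(tibble)

set.seed(42)
cfg <- sim_config(n_chrom = 2, chrom_length = 5e6, site_density = 1e-3)
design <- tribble(
  ~id,          ~type,     ~parent1,    ~parent2,
  "Heunisch",   "founder",  NA,          NA,
  "PinotNoir",  "founder",  NA,          NA,
  "Chardonnay", "cross",    "Heunisch",  "PinotNoir",
  "PinotClone", "clone",    "PinotNoir", NA)
sim <- simulate_cohort(design, cfg)
sim$dataset
#> <genotype_dataset> 10,000 sites x 4 samples (2 chromosomes)
#>   groups: cultivated (4)
#>   masked sites: 4,084; metadata: DP/AD/PL; phase: present

fc <- filter_cohort(sim$dataset)
fc$report
#> <filter_report> 39,404/40,000 calls pass (98.5%); 0 re-admitted by coverage relaxation

ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                   "nonrep_fixed", w = 1e5)
ibd_profile(fc$dataset, c("PinotNoir", "Chardonnay"), ws)
#> <ibd_profile> PinotNoir - Chardonnay
#>   IBD0 0.0% | IBD1 100.0% | IBD2 0.0% of 9.9 classified Mb
#>   sd0 0.000 Mb, sd2 0.000 Mb, sd2 across chromosomes 0.000 Mb

relationship_network(fc$dataset, ws,
                     rules = relationship_rules(clone_ibd1_min = 0))
#> # A tibble: 4 x 13
#>   sample1    sample2    category  pct0  pct1  pct2 hap_distance
#> 1 Heunisch   Chardonnay PO           0   100     0          0.5
#> 2 PinotNoir  Chardonnay PO           0   100     0          0.5
#> 3 PinotNoir  PinotClone clone        0     0   100          0
#> 4 Chardonnay PinotClone PO           0   100     0          0.5
```

Chardonnay is recovered as the Heunisch × Pinot cross, the clone pair shares
its whole genome IBD = 2 (haplotypic distance 0), and both Pinot copies are
parents of Chardonnay. `pct0 = 0` for parent–offspring pairs is exact:
Mendelian transmission makes opposite homozygotes impossible without
genotyping error. (`clone_ibd1_min = 0` is the documented alternative to the
reference clone rule, whose IBD1 > 3% bound cannot be met by an error-free
clone pair; see the methods vignette.)

Downstream scans chain the same way — `polarize()` |> `d_fd_scan()` for
introgression, `haplotype_diversity_scan()` |> `detect_sweeps()` for sweep
valleys, `ase_test()` for expression — and every result is a tibble (or has
`tidy()`/`glance()` methods) with `autoplot()` figures.

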