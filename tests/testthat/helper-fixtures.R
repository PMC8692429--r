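# compact builders for crafted datasets ------------------------------------

# genotype dataset from a dosage matrix; metadata synthesized consistently
# with each call unless overridden
make_ds <- function(gt, dp = NULL, ad_ref = NULL, ad_alt = NULL, pl = NULL,
                    qual = 1000, chrom = "chr01", pos = NULL, masked = FALSE,
                    group = "cultivated", hap1 = NULL, hap2 = NULL,
                    chrom_lengths = NULL, with_metadata = FALSE) {
  gt <- as.matrix(gt)
  n <- nrow(gt); m <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- tibble::tibble(
    chrom = rep(chrom, length.out = n), pos = as.integer(pos),
    ref = "A", alt = "T",
    qual = rep(qual, length.out = n), masked = rep(masked, length.out = n))
  ids <- colnames(gt) %||% sprintf("S%02d", seq_len(m))
  samples <- tibble::tibble(sample = ids, group = rep(group, length.out = m))
  if (with_metadata && is.null(dp)) {
    dp <- matrix(20L, n, m)
    ad_ref <- matrix(0L, n, m)
    ad_ref[gt == 0L] <- dp[gt == 0L]
    ad_ref[gt == 1L] <- dp[gt == 1L] %/% 2L
    ad_alt <- dp - ad_ref
    pl <- pl_from_gt(gt, dp)
  }
  genotype_dataset(sites, samples, gt, dp = dp, ad_ref = ad_ref,
                   ad_alt = ad_alt, pl = pl, hap1 = hap1, hap2 = hap2,
                   chrom_lengths = chrom_lengths)
}

# PL consistent with the call: 0 at the call, 10*mismatch*dp/2 elsewhere
pl_from_gt <- function(gt, dp) {
  n <- nrow(gt); m <- ncol(gt)
  pl <- array(NA_integer_, c(n, m, 3))
  for (g in 0:2) {
    pl[, , g + 1] <- pmin(as.integer(round(10 * abs(gt - g) * dp / 2)), 255L)
  }
  pl
}

# founder-only pedigree design
founder_design <- function(n, prefix = "V", group = "cultivated") {
  tibble::tibble(id = sprintf("%s%02d", prefix, seq_len(n)), type = "founder",
                 parent1 = NA_character_, parent2 = NA_character_,
                 group = group)
}

# write a small hand-authored VCF; returns paths of vcf/mask/groups
write_toy_vcf <- function(dir = NULL, extra_records = character()) {
  if (is.null(dir)) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
  }
  vcf <- file.path(dir, "toy.vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste("chr01", 100, ".", "A", "T", 900, "PASS", ".", "GT:DP:AD:PL",
          "0/1:20:10,10:130,0,130", "0/0:22:22,0:0,110,255",
          "1/1:18:0,18:255,90,0", sep = "\t"),
    paste("chr01", 250, ".", "C", "G", 800, "PASS", ".", "GT:DP:AD:PL",
          "0/0:25:25,0:0,125,255", "0/1:20:11,9:130,0,130",
          "./.:.:.,.:.,.,.", sep = "\t"),
    paste("chr01", 300, ".", "G", "A,T", 700, "PASS", ".", "GT",
          "0/1", "1/2", "0/0", sep = "\t"),  # multiallelic: skipped
    paste("chr01", 480, ".", "T", "C", 950, "PASS", ".", "GT:DP:AD:PL",
          "1|0:30:14,16:130,0,130", "1/1:28:0,28:255,140,0",
          "0/0:26:26,0:0,130,255", sep = "\t"),
    paste("chr01", 900, ".", "A", "G", 60, "PASS", ".", "GT:DP:AD:PL",
          "0/0:20:20,0:0,100,255", "0/0:21:21,0:0,105,255",
          "0/1:19:9,10:95,0,95", sep = "\t"),
    extra_records)
  writeLines(lines, vcf)
  mask <- file.path(dir, "toy.mask.bed")
  writeLines("chr01\t850\t1000", mask)
  groups <- file.path(dir, "toy.groups.tsv")
  writeLines(c("S1\tcultivated", "S2\tcultivated", "S3\twestern_sylvestris"),
             groups)
  list(vcf = vcf, mask = mask, groups = groups, dir = dir)
}

# independent scalar re-implementation of the filter cascade (oracle)
oracle_filter <- function(ds, cfg = filter_config()) {
  n <- n_sites(ds); m <- n_samples(ds)
  modal <- numeric(m)
  for (j in seq_len(m)) {
    dp <- ds$dp[, j]; dp <- dp[!is.na(dp)]
    tab <- table(dp)
    modal[j] <- min(as.integer(names(tab)[tab == max(tab)]))
  }
  rule_pass <- function(i, j, upper_mult) {
    g <- ds$gt[i, j]
    if (is.na(g)) return(FALSE)
    if (!(ds$sites$qual[i] > cfg$qual_min)) return(FALSE)
    dp <- ds$dp[i, j]
    if (is.na(dp) || dp < cfg$dp_min) return(FALSE)
    low <- if (g == 1L) cfg$band_low else cfg$hom_band_low
    if (dp < low * modal[j] || dp > upper_mult * modal[j]) return(FALSE)
    if (g == 1L) {
      r <- ds$ad_ref[i, j] / (ds$ad_ref[i, j] + ds$ad_alt[i, j])
      if (is.na(r) || r < cfg$het_balance[1] || r > cfg$het_balance[2]) {
        return(FALSE)
      }
    } else {
      pls <- ds$pl[i, j, ]
      assigned <- if (g == 0L) pls[1] else pls[3]
      others <- if (g == 0L) pls[2:3] else pls[1:2]
      nz <- others[others != 0]
      if (assigned != 0 || length(nz) == 0 || min(nz) <= cfg$hom_pl_min) {
        return(FALSE)
      }
    }
    fr <- ds$ad_ref[i, j] / dp; fa <- ds$ad_alt[i, j] / dp
    ok <- if (g == 0L) fr > cfg$ad_dp_min else
      if (g == 2L) fa > cfg$ad_dp_min else
        fr > cfg$ad_dp_min && fa > cfg$ad_dp_min
    isTRUE(ok)
  }
  pass1 <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pass1[i, j] <- rule_pass(i, j, cfg$band_high)
  }
  pass <- pass1
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!pass1[i, j] && sum(pass1[i, -j]) >= cfg$relax_support &&
        rule_pass(i, j, cfg$relaxed_high)) {
      pass[i, j] <- TRUE
    }
  }
  retained <- logical(n)
  for (i in seq_len(n)) {
    carriers <- sum(pass[i, ] & !is.na(ds$gt[i, ]) & ds$gt[i, ] > 0)
    retained[i] <- !ds$sites$masked[i] &&
      mean(pass[i, ]) > cfg$site_retention && carriers >= cfg$min_carriers
  }
  list(pass1 = pass1, pass = pass, retained = retained, modal = modal)
}

# standard kinship benchmark design: 10 pairs per class
kinship_benchmark_design <- function(n = 10) {
  dplyr::bind_rows(
    tibble::tibble(id = sprintf("F%02d", seq_len(n)), type = "founder",
                   parent1 = NA_character_, parent2 = NA_character_),
    tibble::tibble(id = sprintf("K%02d", seq_len(n)), type = "clone",
                   parent1 = sprintf("F%02d", seq_len(n)),
                   parent2 = NA_character_),
    tibble::tibble(id = sprintf("M%02d", seq_len(n)), type = "founder",
                   parent1 = NA_character_, parent2 = NA_character_),
    tibble::tibble(id = sprintf("N%02d", seq_len(n)), type = "founder",
                   parent1 = NA_character_, parent2 = NA_character_),
    tibble::tibble(id = sprintf("A%02d", seq_len(n)), type = "cross",
                   parent1 = sprintf("M%02d", seq_len(n)),
                   parent2 = sprintf("N%02d", seq_len(n))),
    tibble::tibble(id = sprintf("B%02d", seq_len(n)), type = "cross",
                   parent1 = sprintf("M%02d", seq_len(n)),
                   parent2 = sprintf("N%02d", seq_len(n))))
}
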