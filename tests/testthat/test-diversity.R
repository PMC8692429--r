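test_that("windowed pi matches its closed form and a pairwise-difference oracle", {
  # 2 diploids (4 haplotypes), one segregating site at p = 0.5, 1000-bp window
  gt <- matrix(c(1L, 1L), 1, 2)
  ds <- make_ds(gt, pos = 500, chrom_lengths = c(chr01 = 1000))
  ws <- make_windows(repeat_mask(), c(chr01 = 1000), "nonrep_fixed", w = 1000)
  tab <- nucleotide_diversity_scan(ds, "cultivated", ws)
  expect_equal(tab$pi, (4 / 3) * 2 * 0.25 / 1000)
  # equals the mean pairwise difference over all 6 haplotype pairs: 4/6 per site
  expect_equal(tab$pi, (4 / 6) / 1000)

  # monomorphic window
  ds0 <- make_ds(matrix(0L, 3, 2), chrom_lengths = c(chr01 = 1000))
  expect_equal(nucleotide_diversity_scan(ds0, "cultivated", ws)$pi, 0)

  # random fixture with missing calls vs brute-force oracle
  set.seed(71)
  n <- 80; m <- 6
  gt <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                      prob = c(.35, .3, .3, .05)), n, m)
  pos <- sort(sample.int(20000, n))
  ds2 <- make_ds(gt, pos = pos, chrom_lengths = c(chr01 = 20000))
  ws2 <- make_windows(repeat_mask(), c(chr01 = 20000), "nonrep_fixed", w = 5000)
  tab2 <- nucleotide_diversity_scan(ds2, "cultivated", ws2)
  # oracle: per site, average difference over all called-haplotype pairs
  site_pair_diff <- vapply(seq_len(n), function(i) {
    g <- gt[i, ][!is.na(gt[i, ])]
    haps <- unlist(lapply(g, function(x) if (x == 0) c(0, 0) else
      if (x == 1) c(0, 1) else c(1, 1)))
    if (length(haps) < 2) return(0)
    pr <- utils::combn(haps, 2)
    mean(pr[1, ] != pr[2, ])
  }, numeric(1))
  for (k in seq_len(nrow(tab2))) {
    inside <- which(pos - 1 >= tab2$start[k] & pos - 1 < tab2$end[k])
    expect_equal(tab2$pi[k], sum(site_pair_diff[inside]) / tab2$nonrep_bp[k])
  }
})

test_that("block haplotype diversity matches its closed forms", {
  # 4 haplotypes in two equifrequent types over one 5-site block
  h_a <- c(0L, 1L, 0L, 1L, 1L)
  h_b <- c(1L, 0L, 1L, 0L, 0L)
  hap1 <- cbind(h_a, h_b)
  hap2 <- cbind(h_a, h_b)
  ds <- make_ds(hap1 + hap2, hap1 = hap1, hap2 = hap2,
                chrom_lengths = c(chr01 = 1000))
  trk <- haplotype_diversity_scan(ds, "cultivated", block_size = 5, n_avg = 1)
  expect_equal(trk$blocks$H, (4 / 3) * (1 - 0.5))
  expect_equal(trk$blocks$H, 0.6667, tolerance = 1e-4)
  # identical haplotypes: H = 0
  ds0 <- make_ds(matrix(2L, 5, 2), hap1 = matrix(1L, 5, 2),
                 hap2 = matrix(1L, 5, 2), chrom_lengths = c(chr01 = 1000))
  trk0 <- haplotype_diversity_scan(ds0, "cultivated", block_size = 5, n_avg = 1)
  expect_equal(trk0$blocks$H, 0)
  # chromosomes with fewer sites than a block contribute nothing
  ds1 <- make_ds(matrix(0L, 3, 2), hap1 = matrix(0L, 3, 2),
                 hap2 = matrix(0L, 3, 2))
  trk1 <- haplotype_diversity_scan(ds1, "cultivated", block_size = 5)
  expect_equal(nrow(trk1$blocks), 0)
})

test_that("sweep detection honors the quantile threshold and merge gap", {
  mk_track <- function(smooth) {
    structure(list(points = tibble::tibble(
      chrom = "chr01", pos = seq_along(smooth) * 1e5,
      H = smooth, smooth = smooth)), class = "diversity_track")
  }
  # flat track: nothing strictly below its own quantile
  expect_equal(nrow(detect_sweeps(mk_track(rep(0.8, 100)))), 0)
  # two distinct valleys further apart than the merge gap
  v <- rep(0.8, 100)
  v[20:21] <- c(0.01, 0.02); v[60:61] <- c(0.015, 0.02)
  v[22] <- 0.03; v[62] <- 0.03   # threshold lands above the deep points
  calls <- detect_sweeps(mk_track(v), quantile = 0.05, merge_gap = 2)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$nadir, c(20e5, 60e5))
  # two below-threshold points merge across a small above-threshold gap
  v2 <- rep(0.8, 100)
  v2[20] <- 0.01; v2[23] <- 0.02; v2[21:22] <- 0.85
  calls2 <- detect_sweeps(mk_track(v2), quantile = 0.05, merge_gap = 2)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$n_points, 4)
  # but not across a gap wider than merge_gap
  calls3 <- detect_sweeps(mk_track(v2), quantile = 0.05, merge_gap = 1)
  expect_equal(nrow(calls3), 2)
})

test_that("a planted sweep is recovered as one valley at the right place", {
  set.seed(72)
  cfg <- sim_config(n_chrom = 1, chrom_length = 3e6, site_density = 4e-3,
                    error_rate = 0, mask_fraction = 0.3)
  sim <- simulate_cohort(founder_design(15), cfg, with_metadata = FALSE)
  region <- list(chrom = "chr01", start = 1.2e6, end = 1.7e6)
  sw <- simulate_sweep(sim$dataset, region, swept_freq = 0.95)
  trk <- haplotype_diversity_scan(sw$dataset, "cultivated")
  calls <- detect_sweeps(trk)
  expect_equal(nrow(calls), 1)
  spacing <- 250 / 4e-3 / 1e0  # plotted point spacing in bp
  expect_gte(calls$nadir, region$start - spacing)
  expect_lte(calls$nadir, region$end + spacing)
})

test_that("runs of homozygosity behave on degenerate and planted inputs", {
  # all-heterozygous sample: no ROH
  ds_het <- make_ds(matrix(1L, 300, 1), pos = (1:300) * 1e4,
                    chrom_lengths = c(chr01 = 4e6))
  expect_equal(nrow(roh_scan(ds_het, "S01")), 0)
  # fully homozygous chromosome of 200 sites spanning 2 Mb: one ROH spans it
  ds_hom <- make_ds(matrix(0L, 200, 1), pos = (1:200) * 1e4,
                    chrom_lengths = c(chr01 = 2.1e6))
  r <- roh_scan(ds_hom, "S01")
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1e4)
  expect_equal(r$end, 2e6)
  expect_equal(r$n_sites, 200L)
  # planted homozygous tract in a heterozygous background
  set.seed(73)
  g <- sample(c(1L, 1L, 0L, 2L), 2000, replace = TRUE)
  tract <- 800:1200
  g[tract] <- sample(c(0L, 2L), length(tract), replace = TRUE)
  ds_tr <- make_ds(matrix(g, ncol = 1), pos = (1:2000) * 1000,
                   chrom_lengths = c(chr01 = 2.1e6))
  r2 <- roh_scan(ds_tr, "S01", min_sites = 50, max_het = 1, min_len_bp = 1e5)
  truth <- c(800 * 1000, 1200 * 1000)
  ovl <- max(0, min(r2$end[1], truth[2]) - max(r2$start[1], truth[1]))
  expect_gte(ovl / (truth[2] - truth[1]), 0.9)
  expect_gte(ovl / (r2$end[1] - r2$start[1]), 0.9)
})

test_that("regional haplotype inference resolves what is deducible and no more", {
  # panel seeded by the reference and a homozygous-alternative accession
  H1 <- c(0L, 0L, 0L, 0L)
  H2 <- c(1L, 1L, 0L, 1L)
  H3 <- c(0L, 1L, 1L, 0L)
  gt <- cbind(
    ACC1 = H1 + H1,      # reference homozygote
    ACC2 = H2 + H2,      # novel homozygote: one haplotype, counted twice
    ACC3 = H1 + H3,      # het consistent with the reference: complement H3
    ACC4 = H2 + H3)      # resolvable only after H3 enters the panel
  ds <- make_ds(gt, chrom_lengths = c(chr01 = 1000))
  region <- list(chrom = "chr01", start = 0, end = 1000)
  panel <- infer_region_haplotypes(ds, region, H1)
  a <- panel$assignments
  expect_true(all(a$resolved[1:3]))
  hap_of <- function(id) sort(unlist(a[a$sample == id, c("hap1", "hap2")]))
  expect_equal(unname(hap_of("ACC1")), c("H1", "H1"))
  expect_equal(length(unique(unlist(hap_of("ACC2")))), 1)
  # ACC4 = H2 + H3 becomes resolvable once H3 has entered the panel
  expect_true(a$resolved[4])
  expect_equal(sum(panel$haplotypes$count), 8)
  expect_equal(sum(panel$haplotypes$freq), 1)
  # resolved diplotypes reproduce genotypes at every site
  key <- stats::setNames(lapply(seq_len(nrow(panel$haplotypes)), function(i) {
    as.integer(strsplit(panel$haplotypes$alleles[i], "")[[1]])
  }), panel$haplotypes$hap_id)
  for (j in which(a$resolved)) {
    expect_equal(key[[a$hap1[j]]] + key[[a$hap2[j]]], unname(gt[, j]))
  }
})

test_that("ambiguous accessions stay unresolved and truth panels are recovered", {
  # two complementary decompositions of a double heterozygote: ambiguous
  Ha <- c(0L, 0L); Hb <- c(1L, 1L); Hc <- c(1L, 0L); Hd <- c(0L, 1L)
  gt <- cbind(A1 = Ha + Ha, A2 = Hb + Hb, A3 = Hc + Hc, A4 = Hd + Hd,
              A5 = c(1L, 1L))
  ds <- make_ds(gt, chrom_lengths = c(chr01 = 1000))
  panel <- infer_region_haplotypes(ds, list(chrom = "chr01", start = 0,
                                            end = 1000), Ha)
  expect_false(panel$assignments$resolved[5])

  # a fully resolvable planted 8-haplotype panel is recovered exactly
  set.seed(74)
  hp <- simulate_haplotype_panel(n_sites = 30, n_hap = 8)
  panel8 <- infer_region_haplotypes(hp$dataset,
                                    list(chrom = "chr01", start = 0, end = 1e5),
                                    hp$haplotypes[, 1])
  expect_true(all(panel8$assignments$resolved))
  truth_keys <- apply(hp$haplotypes, 2, paste, collapse = "")
  found <- panel8$haplotypes$alleles[panel8$haplotypes$count > 0]
  expect_setequal(found, truth_keys)
  truth_counts <- table(factor(
    c(truth_keys[hp$diplotypes$hap1], truth_keys[hp$diplotypes$hap2]),
    levels = sort(truth_keys)))
  got <- panel8$haplotypes[order(panel8$haplotypes$alleles), ]
  got <- got[got$count > 0, ]
  expect_equal(got$count, as.integer(truth_counts))

  # an extra monomorphic site changes no assignment
  gt2 <- rbind(gt, 0L)
  ds2 <- make_ds(gt2, chrom_lengths = c(chr01 = 1000))
  panel2 <- infer_region_haplotypes(ds2, list(chrom = "chr01", start = 0,
                                              end = 1000), c(Ha, 0L))
  expect_equal(panel2$assignments$resolved, panel$assignments$resolved)

  # a reference haplotype nobody carries is rejected
  expect_error(infer_region_haplotypes(ds, list(chrom = "chr01", start = 0,
                                                end = 1000), c(9L, 9L)),
               "inconsistent")
})
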