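# a profile-like object from bare summaries, for classifier unit tests
fake_profile <- function(pct0, pct1, pct2, sd0 = 0, sd2 = 0, sd2_chr = 0) {
  total <- 100
  list(summary = list(pct0 = pct0, pct1 = pct1, pct2 = pct2,
                      L0 = pct0, L1 = pct1, L2 = pct2,
                      classified_mb = total,
                      sd0_genome = sd0, sd2_genome = sd2, sd2_chr = sd2_chr))
}

test_that("identical genotypes give IBD = 2 everywhere", {
  set.seed(51)
  cfg <- sim_config(n_chrom = 2, chrom_length = 2e6, site_density = 1e-3,
                    error_rate = 0)
  design <- dplyr::bind_rows(
    founder_design(2, "F"),
    tibble::tibble(id = "K1", type = "clone", parent1 = "F01",
                   parent2 = NA_character_, group = "cultivated"))
  sim <- simulate_cohort(design, cfg, with_metadata = FALSE)
  ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                     "nonrep_fixed", w = 1e5)
  prof <- ibd_profile(sim$dataset, c("F01", "K1"), ws)
  st <- prof$windows$state
  expect_true(all(st[!is.na(st)] == 2L))
  expect_equal(prof$summary$pct2, 100)
  expect_equal(haplotypic_distance(prof), 0)
})

test_that("parent-offspring pairs show no IBD = 0 at error rate 0", {
  set.seed(52)
  cfg <- sim_config(n_chrom = 3, chrom_length = 5e6, site_density = 1e-3,
                    error_rate = 0)
  design <- dplyr::bind_rows(
    founder_design(2, "F"),
    tibble::tibble(id = "C1", type = "cross", parent1 = "F01", parent2 = "F02",
                   group = "cultivated"))
  sim <- simulate_cohort(design, cfg, with_metadata = FALSE)
  ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                     "nonrep_fixed", w = 1e5)
  prof <- ibd_profile(sim$dataset, c("F01", "C1"), ws)
  expect_equal(prof$summary$pct0, 0)
  expect_gt(prof$summary$pct1, 50)
  expect_equal(classify_relationship(prof)$category, "PO")
})

test_that("full sibs spend about a quarter of the genome in IBD 0 and in IBD 2", {
  set.seed(53)
  design <- dplyr::bind_rows(
    founder_design(2, "F"),
    tibble::tibble(id = c("A", "B"), type = "cross", parent1 = "F01",
                   parent2 = "F02", group = "cultivated"))
  sim <- simulate_cohort(design, sim_config(error_rate = 0),
                         with_metadata = FALSE)
  # windows wide enough that each carries dozens of informative sites
  ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                     "nonrep_fixed", w = 4e5)
  prof <- ibd_profile(sim$dataset, c("A", "B"), ws)
  expect_lt(abs(prof$summary$pct0 - 25), 12)
  expect_lt(abs(prof$summary$pct2 - 25), 12)
  expect_gt(prof$summary$sd2_genome, 0.23)  # multi-Mb IBD segments disperse
})

test_that("profiles are symmetric and segment statistics recompute exactly", {
  set.seed(54)
  design <- dplyr::bind_rows(
    founder_design(2, "F"),
    tibble::tibble(id = c("A", "B"), type = "cross", parent1 = "F01",
                   parent2 = "F02", group = "cultivated"))
  cfg <- sim_config(n_chrom = 4, chrom_length = 5e6, site_density = 1e-3)
  sim <- simulate_cohort(design, cfg, with_metadata = FALSE)
  ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                     "nonrep_fixed", w = 3e5)
  pab <- ibd_profile(sim$dataset, c("A", "B"), ws)
  pba <- ibd_profile(sim$dataset, c("B", "A"), ws)
  expect_equal(pab$windows$state, pba$windows$state)
  expect_equal(pab$summary, pba$summary)
  seg <- pab$segments
  sd_or_zero <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  expect_equal(pab$summary$sd0_genome,
               sd_or_zero(seg$length_mb[seg$state == 0]))
  expect_equal(pab$summary$sd2_genome,
               sd_or_zero(seg$length_mb[seg$state == 2]))
  chr_means <- tapply(seg$length_mb[seg$state == 2],
                      seg$chrom[seg$state == 2], mean)
  expect_equal(pab$summary$sd2_chr, sd_or_zero(as.numeric(chr_means)))
  # segments tile the classified windows
  expect_equal(sum(seg$n_windows), sum(!is.na(pab$windows$state)))
})

test_that("haplotypic distance hits its closed forms", {
  clone_prof <- list(summary = list(L0 = 0, L1 = 0, L2 = 10, classified_mb = 10))
  po_prof <- list(summary = list(L0 = 0, L1 = 10, L2 = 0, classified_mb = 10))
  far_prof <- list(summary = list(L0 = 10, L1 = 0, L2 = 0, classified_mb = 10))
  expect_equal(haplotypic_distance(clone_prof), 0)
  expect_equal(haplotypic_distance(po_prof), 0.5)
  expect_equal(haplotypic_distance(far_prof), 1)
  empty <- list(summary = list(L0 = 0, L1 = 0, L2 = 0, classified_mb = 0))
  expect_warning(d <- haplotypic_distance(empty), "undefined")
  expect_true(is.na(d))
})

test_that("the printed decision list classifies canonical profiles", {
  expect_equal(classify_relationship(
    fake_profile(2, 88, 10, sd0 = 0.05))$category, "PO")
  expect_equal(classify_relationship(
    fake_profile(1, 5, 94))$category, "clone")
  expect_equal(classify_relationship(
    fake_profile(60, 35, 5))$category, "gt2nd")
  expect_equal(classify_relationship(
    fake_profile(15, 55, 30, sd0 = 0.15, sd2 = 0.5, sd2_chr = 4))$category,
    "FS")
  expect_equal(classify_relationship(
    fake_profile(30, 65, 5, sd0 = 0.5, sd2 = 0.1, sd2_chr = 1))$category,
    "HS")
  # the printed clone rule excludes perfectly identical pairs ...
  expect_equal(classify_relationship(
    fake_profile(0, 0, 100))$category, "gt2nd")
  # ... unless the documented alternative lower bound of 0 is chosen
  expect_equal(classify_relationship(
    fake_profile(0, 0, 100), relationship_rules(clone_ibd1_min = 0))$category,
    "clone")
  # every threshold comparison is traced
  call <- classify_relationship(fake_profile(60, 35, 5))
  expect_true(all(c("clone", "PO", "FS", "HS") %in% call$trace$rule))
  expect_error(classify_relationship(list(summary = list(pct0 = 1))),
               "missing summary")
})

test_that("a trio yields exactly its two parent-offspring edges", {
  set.seed(55)
  cfg <- sim_config(n_chrom = 3, chrom_length = 5e6, site_density = 1e-3,
                    error_rate = 0)
  design <- dplyr::bind_rows(
    founder_design(2, "F"),
    tibble::tibble(id = "C1", type = "cross", parent1 = "F01", parent2 = "F02",
                   group = "cultivated"))
  sim <- simulate_cohort(design, cfg, with_metadata = FALSE)
  ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                     "nonrep_fixed", w = 1e5)
  net <- relationship_network(sim$dataset, ws)
  expect_equal(nrow(net), 2)
  expect_true(all(net$category == "PO"))
  expect_setequal(paste(net$sample1, net$sample2),
                  c("F01 C1", "F02 C1"))
})

test_that("a clonal cohort forms a complete clone graph", {
  set.seed(56)
  design <- dplyr::bind_rows(
    founder_design(1, "F"),
    tibble::tibble(id = sprintf("K%d", 1:3), type = "clone", parent1 = "F01",
                   parent2 = NA_character_, group = "cultivated"))
  cfg <- sim_config(n_chrom = 2, chrom_length = 2e6, site_density = 1e-3,
                    error_rate = 0)
  sim <- simulate_cohort(design, cfg, with_metadata = FALSE)
  ws <- make_windows(attr(sim$dataset, "mask"), sim$dataset$chrom_lengths,
                     "nonrep_fixed", w = 1e5)
  net <- relationship_network(sim$dataset, ws,
                              rules = relationship_rules(clone_ibd1_min = 0))
  expect_equal(nrow(net), choose(4, 2))
  expect_true(all(net$category == "clone"))
})

test_that("windows short of informative sites stay unclassified", {
  gt <- matrix(sample(0:2, 5 * 2, replace = TRUE), 5, 2)
  ds <- make_ds(gt, chrom_lengths = c(chr01 = 1000))
  ws <- make_windows(repeat_mask(), c(chr01 = 1000), "nonrep_fixed", w = 1000)
  prof <- ibd_profile(ds, c("S01", "S02"), ws)   # 5 < min_sites = 10
  expect_true(all(is.na(prof$windows$state)))
  expect_true(prof$low_confidence)
  expect_equal(prof$summary$classified_mb, 0)
})
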