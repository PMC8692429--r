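# a polarized_sites-like object straight from a frequency matrix
fake_pol <- function(freqs, pos = NULL, chrom = "chr01") {
  n <- nrow(freqs)
  structure(list(
    sites = tibble::tibble(
      chrom = rep(chrom, length.out = n),
      pos = if (is.null(pos)) seq_len(n) * 10L else pos,
      ancestral = "A", derived = "T",
      polarizable = TRUE, trans_specific = NA, masked = FALSE),
    freqs = freqs), class = "polarized_sites")
}

one_window <- function(len = 1e6) {
  make_windows(repeat_mask(), c(chr01 = len), "sliding", span = len, step = len)
}

test_that("polarization follows the outgroup's single allele", {
  # samples: 2 vinifera, 2 outgroup, 2 other species
  gt <- rbind(
    c(1L, 2L, 0L, 0L, 0L, 0L),  # outgroup all-ref: derived = alt
    c(1L, 0L, 1L, 0L, 0L, 0L),  # outgroup het: non-polarizable
    c(0L, 1L, 2L, 2L, 0L, 0L),  # outgroup all-alt: ancestral = alt
    c(1L, 1L, 0L, 2L, 0L, 0L),  # outgroup segregating: non-polarizable
    c(1L, 1L, 0L, 0L, 0L, 1L))  # other species carry both alleles
  ds <- make_ds(gt, group = c("cultivated", "cultivated", "outgroup",
                              "outgroup", "species", "species"))
  pol <- polarize(ds, outgroup_samples = c("S03", "S04"),
                  other_species = c("S05", "S06"))
  expect_equal(pol$sites$polarizable, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(pol$sites$derived[1], "T")
  expect_equal(pol$sites$ancestral[3], "T")
  expect_equal(pol$sites$derived[3], "A")
  # derived frequency is flipped where the alt allele is ancestral
  expect_equal(unname(pol$freqs[1, "cultivated"]), 0.75)
  expect_equal(unname(pol$freqs[3, "cultivated"]), 1 - 0.25)
  expect_true(is.na(pol$freqs[2, "cultivated"]))
  expect_equal(pol$sites$trans_specific, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_no_error(polarize(subset_sites(ds, 1:2), "S05"))
})

test_that("the unfolded SFS conserves polarizable fully-called sites", {
  set.seed(61)
  sim <- simulate_four_taxon(
    sim_config(n_chrom = 1, chrom_length = 5e5, site_density = 2e-3,
               error_rate = 0), f = 0, with_metadata = FALSE)
  ds <- sim$dataset
  pol <- polarize(ds, group_samples(ds, "outgroup"))
  sfs <- unfolded_sfs(pol, ds, "table")
  n_target <- length(group_samples(ds, "table"))
  full <- rowSums(is.na(ds$gt[, ds$samples$group == "table"])) == 0
  expect_equal(sum(sfs$n_sites), sum(pol$sites$polarizable & full))
  expect_equal(nrow(sfs), 2 * n_target + 1)
})

test_that("D and f_d hit their closed forms on single-site patterns", {
  ws <- one_window(100)
  # p1 = p2 everywhere: D exactly 0
  fr <- cbind(P1 = c(0.3, 0.7), P2 = c(0.3, 0.7), P3 = c(0.9, 0.2),
              O = c(0, 0))
  s0 <- d_fd_scan(fake_pol(fr), "P1", "P2", "P3", "O", ws)
  expect_equal(s0$windows$D[1], 0)
  # pure ABBA site: D = 1
  fr1 <- cbind(P1 = 0, P2 = 1, P3 = 1, O = 0)
  s1 <- d_fd_scan(fake_pol(fr1), "P1", "P2", "P3", "O", ws)
  expect_equal(s1$windows$D[1], 1)
  # f_d with the donor as denominator majority: 0.5
  fr2 <- cbind(P1 = 0, P2 = 0.5, P3 = 1, O = 0)
  s2 <- d_fd_scan(fake_pol(fr2), "P1", "P2", "P3", "O", ws)
  expect_equal(s2$windows$fd[1], 0.5)
  # a window with no informative pattern leaves D undefined, not 0
  fr3 <- cbind(P1 = 0.5, P2 = 0.5, P3 = 0, O = 0)
  s3 <- d_fd_scan(fake_pol(fr3), "P1", "P2", "P3", "O", ws)
  expect_true(is.na(s3$windows$D[1]))
})

test_that("window pattern sums equal an independent per-site loop", {
  set.seed(62)
  n <- 600
  fr <- cbind(P1 = stats::runif(n), P2 = stats::runif(n), P3 = stats::runif(n),
              O = stats::runif(n, 0, 0.1))
  pos <- sort(sample.int(5000, n))
  pol <- fake_pol(fr, pos = pos)
  ws <- make_windows(repeat_mask(), c(chr01 = 5000), "sliding",
                     span = 1000, step = 400)
  scan <- d_fd_scan(pol, "P1", "P2", "P3", "O", ws)
  for (i in seq_len(nrow(ws))) {
    abba <- baba <- 0
    for (s in seq_len(n)) {
      if (pos[s] - 1 >= ws$start[i] && pos[s] - 1 < ws$end[i]) {
        f <- as.numeric(fr[s, ])
        abba <- abba + (1 - f[1]) * f[2] * f[3] * (1 - f[4])
        baba <- baba + f[1] * (1 - f[2]) * f[3] * (1 - f[4])
      }
    }
    expect_equal(scan$windows$abba[i], abba)
    expect_equal(scan$windows$baba[i], baba)
    expect_equal(scan$windows$D[i], (abba - baba) / (abba + baba))
  }
  # swapping P1 and P2 negates D exactly
  swapped <- d_fd_scan(pol, "P2", "P1", "P3", "O", ws)
  expect_equal(swapped$windows$D, -scan$windows$D)
  expect_equal(swapped$genome$D, -scan$genome$D)
  # f_d is undefined exactly where D <= 0
  expect_equal(is.na(scan$windows$fd),
               is.na(scan$windows$D) | scan$windows$D <= 0)
  # fd_zero emits 0 for non-positive-D windows instead
  z <- d_fd_scan(pol, "P1", "P2", "P3", "O", ws, fd_zero = TRUE)
  expect_true(all(z$windows$fd[which(z$windows$D <= 0)] == 0))
})

test_that("f3 is non-negative for a drifted copy and negative for a mixture", {
  set.seed(63)
  n <- 3000
  pa <- stats::runif(n, 0.05, 0.35)
  pb <- stats::runif(n, 0.65, 0.95)
  # target identical to source A
  fr_same <- cbind(T = pa, A = pa, B = pb)
  expect_gte(f3_test(fake_pol(fr_same), "T", "A", "B")$f3, 0)
  # target = 50/50 mixture of the two sources (small independent noise)
  pt <- pmin(pmax((pa + pb) / 2 + stats::rnorm(n, 0, 0.02), 0), 1)
  fr_mix <- cbind(T = pt, A = pa, B = pb)
  res <- f3_test(fake_pol(fr_mix), "T", "A", "B")
  expect_lt(res$f3, 0)
  expect_lt(res$z, -3)
  # a single block leaves the jackknife undefined
  one <- f3_test(fake_pol(fr_mix[1:100, ]), "T", "A", "B", block_snps = 1000)
  expect_true(is.na(one$se) && is.na(one$z))
  expect_equal(one$f3, mean((fr_mix[1:100, 1] - fr_mix[1:100, 2]) *
                              (fr_mix[1:100, 1] - fr_mix[1:100, 3])))
  expect_error(f3_test(fake_pol(fr_mix), "T", "T", "B"), "distinct")
})

test_that("D_A is a proper distance and flags donor-matching windows", {
  set.seed(64)
  x <- stats::runif(50); y <- stats::runif(50)
  expect_equal(da_distance(x, x), 0)
  expect_equal(da_distance(x, y), da_distance(y, x))
  expect_gte(da_distance(x, y), 0)
  expect_lte(da_distance(x, y), 1)
  # focal identical to donor in the window -> D_A = 0 -> flagged
  gt <- matrix(c(0L, 1L, 2L), 12, 6)   # same pattern in every column triple
  ds <- make_ds(gt, group = rep(c("focal", "donor", "other"), each = 2),
                chrom_lengths = c(chr01 = 2000))
  ds$gt[, 5:6] <- matrix(c(2L, 0L, 1L), 12, 2)  # the other group differs
  ws <- make_windows(repeat_mask(), c(chr01 = 2000), "nonrep_fixed", w = 2000)
  scan <- da_topology_scan(ds, "focal", "donor", "other", ws)
  expect_equal(scan$da_donor[1], 0)
  expect_true(scan$flagged[1])
  expect_equal(attr(scan, "genome_fraction"), 1)
})
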