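#' Simulation configuration
#'
#' Parameters of the synthetic diploid cohort generator. The defaults are the
#' package's reference study conditions: a 12-chromosome, 20 Mb/chromosome
#' genome (a grapevine-like genome scaled down), ~1.4e-4 segregating sites per
#' bp (about 20,000 unmasked sites genome-wide), founder allele frequencies
#' drawn from Beta(0.5, 0.5) truncated to [0.02, 0.98] in linkage
#' equilibrium, 1.5 crossovers per chromosome per meiosis, 40% of the genome
#' repeat-masked in ~50 kb fragments, modal sequencing coverage 26x and a
#' per-call genotyping error rate of 0.002.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (scalar, recycled).
#' @param site_density Expected segregating sites per bp.
#' @param freq_shape1,freq_shape2,freq_min,freq_max Founder allele-frequency
#'   law: Beta(shape1, shape2) truncated to `[freq_min, freq_max]`.
#' @param recomb_rate Expected crossovers per chromosome per meiosis.
#' @param error_rate Per-call genotyping error rate (a miscalled genotype is
#'   replaced by one of the two other states uniformly).
#' @param coverage Modal per-sample sequencing coverage (scalar or one value
#'   per sample); per-call depth is Poisson around it (floored at 1 read).
#' @param mask_fraction Fraction of each chromosome that is repeat-masked.
#' @param mask_mean_len Mean masked-fragment length (bp, exponential law).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 12, chrom_length = 20e6, site_density = 1.4e-4,
                       freq_shape1 = 0.5, freq_shape2 = 0.5,
                       freq_min = 0.02, freq_max = 0.98,
                       recomb_rate = 1.5, error_rate = 0.002, coverage = 26,
                       mask_fraction = 0.4, mask_mean_len = 5e4) {
  stopifnot(site_density > 0, error_rate >= 0, error_rate <= 1,
            mask_fraction >= 0, mask_fraction < 1,
            freq_min >= 0, freq_max <= 1, freq_min < freq_max)
  structure(
    list(n_chrom = n_chrom, chrom_length = chrom_length,
         site_density = site_density,
         freq_shape1 = freq_shape1, freq_shape2 = freq_shape2,
         freq_min = freq_min, freq_max = freq_max,
         recomb_rate = recomb_rate, error_rate = error_rate,
         coverage = coverage,
         mask_fraction = mask_fraction, mask_mean_len = mask_mean_len),
    class = "sim_config")
}

sim_chrom_lengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, length.out = cfg$n_chrom),
                  sprintf("chr%02d", seq_len(cfg$n_chrom)))
}

# alternating unmasked/masked runs with exponential fragment lengths
simulate_mask <- function(cfg, chrom_lengths) {
  if (cfg$mask_fraction <= 0) return(repeat_mask())
  mean_gap <- cfg$mask_mean_len * (1 - cfg$mask_fraction) / cfg$mask_fraction
  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n_est <- ceiling(len / (mean_gap + cfg$mask_mean_len) * 1.6) + 10
    gaps <- stats::rexp(n_est, 1 / mean_gap)
    frags <- stats::rexp(n_est, 1 / cfg$mask_mean_len)
    ends <- cumsum(gaps + frags)
    while (ends[length(ends)] < len) {
      gaps <- c(gaps, stats::rexp(n_est, 1 / mean_gap))
      frags <- c(frags, stats::rexp(n_est, 1 / cfg$mask_mean_len))
      ends <- cumsum(gaps + frags)
    }
    start <- round(cumsum(gaps + c(0, frags[-length(frags)])))
    end <- round(ends)
    keep <- start < len & end > start
    rows[[ch]] <- tibble::tibble(chrom = ch, start = start[keep],
                                 end = pmin(end[keep], len))
  }
  repeat_mask(dplyr::bind_rows(rows))
}

simulate_sites <- function(cfg, chrom_lengths, mask) {
  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n <- round(len * cfg$site_density)
    pos <- sort(sample.int(len, n))
    rows[[ch]] <- tibble::tibble(chrom = ch, pos = pos)
  }
  sites <- dplyr::bind_rows(rows)
  alle <- matrix(c("A", "C", "G", "T")[t(vapply(seq_len(nrow(sites)),
    function(i) sample.int(4, 2), integer(2)))], ncol = 2)
  sites$ref <- alle[, 1]
  sites$alt <- alle[, 2]
  sites$qual <- round(stats::runif(nrow(sites), 200, 2000))
  sites$masked <- sites_in_mask(mask, sites$chrom, sites$pos)
  sites
}

# Beta law truncated by inverse-cdf sampling
draw_founder_freqs <- function(n, cfg) {
  lo <- stats::pbeta(cfg$freq_min, cfg$freq_shape1, cfg$freq_shape2)
  hi <- stats::pbeta(cfg$freq_max, cfg$freq_shape1, cfg$freq_shape2)
  stats::qbeta(stats::runif(n, lo, hi), cfg$freq_shape1, cfg$freq_shape2)
}

# one gamete: recombine a parent's two haplotypes, Poisson crossovers with
# uniform breakpoints per chromosome, random starting haplotype
meiosis_gamete <- function(h1, h2, sites, chrom_lengths, rate) {
  out <- integer(length(h1))
  for (ch in names(chrom_lengths)) {
    sel <- which(sites$chrom == ch)
    if (!length(sel)) next
    k <- stats::rpois(1, rate)
    bp <- sort(stats::runif(k, 0, chrom_lengths[[ch]]))
    phase <- (sample(0:1, 1) + findInterval(sites$pos[sel], bp)) %% 2
    out[sel] <- ifelse(phase == 0L, h1[sel], h2[sel])
  }
  out
}

#' Simulate a pedigree cohort with ground truth
#'
#' Founders are drawn site-wise from the configured allele-frequency law in
#' linkage equilibrium; derived individuals are built by meiosis (crosses and
#' selfs), or by copying (clones). Per-call genotyping error, depth, allele
#' depths and genotype likelihoods are then layered on the true genotypes.
#' The stored phase is the truth phase except at miscalled genotypes, where
#' it is set to `NA` so phase and genotype stay mutually consistent.
#'
#' @param design Tibble with columns `id`, `type` (one of `"founder"`,
#'   `"cross"`, `"self"`, `"clone"`), `parent1`, `parent2` (`NA` where not
#'   applicable) and optionally `group` (sample label, default
#'   `"cultivated"`). Parents must be defined on earlier rows.
#' @param cfg A [sim_config()].
#' @param with_metadata Attach DP/AD/PL/QUAL (default `TRUE`).
#' @return List with elements `dataset` (a [genotype_dataset()] carrying the
#'   mask as an attribute) and `truth` (a `truth_set`: pedigree, pairwise
#'   relationship labels, founder frequencies, true haplotypes, mask).
#' @export
simulate_cohort <- function(design, cfg = sim_config(), with_metadata = TRUE) {
  design <- tibble::as_tibble(design)
  if (!"group" %in% names(design)) design$group <- "cultivated"
  stopifnot(all(design$type %in% c("founder", "cross", "self", "clone")))
  chrom_lengths <- sim_chrom_lengths(cfg)
  mask <- simulate_mask(cfg, chrom_lengths)
  sites <- simulate_sites(cfg, chrom_lengths, mask)
  n <- nrow(sites); m <- nrow(design)
  p <- draw_founder_freqs(n, cfg)
  H1 <- matrix(NA_integer_, n, m, dimnames = list(NULL, design$id))
  H2 <- H1
  for (i in seq_len(m)) {
    type <- design$type[i]
    if (type == "founder") {
      H1[, i] <- stats::rbinom(n, 1, p)
      H2[, i] <- stats::rbinom(n, 1, p)
      next
    }
    p1 <- match(design$parent1[i], design$id[seq_len(i - 1)])
    if (is.na(p1)) {
      stop("unknown parent '", design$parent1[i], "' for ", design$id[i],
           call. = FALSE)
    }
    if (type == "clone") {
      H1[, i] <- H1[, p1]; H2[, i] <- H2[, p1]
    } else {
      p2 <- if (type == "self") p1 else
        match(design$parent2[i], design$id[seq_len(i - 1)])
      if (is.na(p2)) {
        stop("unknown parent '", design$parent2[i], "' for ", design$id[i],
             call. = FALSE)
      }
      H1[, i] <- meiosis_gamete(H1[, p1], H2[, p1], sites, chrom_lengths,
                                cfg$recomb_rate)
      H2[, i] <- meiosis_gamete(H1[, p2], H2[, p2], sites, chrom_lengths,
                                cfg$recomb_rate)
    }
  }
  gt <- H1 + H2
  hap1 <- H1; hap2 <- H2
  if (cfg$error_rate > 0) {
    err <- which(stats::runif(n * m) < cfg$error_rate)
    gt[err] <- (gt[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    hap1[err] <- NA_integer_; hap2[err] <- NA_integer_
  }
  samples <- tibble::tibble(sample = design$id, group = design$group)
  ds <- genotype_dataset(sites, samples, gt, hap1 = hap1, hap2 = hap2,
                         chrom_lengths = chrom_lengths, validate = FALSE)
  if (with_metadata) ds <- attach_call_metadata(ds, cfg)
  attr(ds, "mask") <- mask
  attr(ds, "sim_config") <- cfg
  truth <- structure(
    list(pedigree = design,
         relations = truth_relationships(design),
         founder_freqs = p, hap1 = H1, hap2 = H2, mask = mask),
    class = "truth_set")
  list(dataset = ds, truth = truth)
}

# DP Poisson around modal coverage; AD binomial given DP and the called
# genotype (het p = 0.5); PL zero at the call, 10 * mismatches * DP/2
# elsewhere, capped at 255
attach_call_metadata <- function(ds, cfg) {
  n <- n_sites(ds); m <- n_samples(ds)
  cov <- rep(cfg$coverage, length.out = m)
  dp <- matrix(pmax(stats::rpois(n * m, rep(cov, each = n)), 1L), n, m)
  gt <- ds$gt
  ad_ref <- matrix(0L, n, m)
  ad_ref[gt == 0L] <- dp[gt == 0L]
  het <- which(gt == 1L)
  ad_ref[het] <- stats::rbinom(length(het), dp[het], 0.5)
  ad_alt <- dp - ad_ref
  miss <- is.na(gt)
  ad_ref[miss] <- NA_integer_; ad_alt[miss] <- NA_integer_
  dp[miss] <- NA_integer_
  pl <- array(NA_integer_, c(n, m, 3))
  for (g in 0:2) {
    pl[, , g + 1] <- pmin(as.integer(round(10 * abs(gt - g) * dp / 2)), 255L)
  }
  ds$dp <- dp; ds$ad_ref <- ad_ref; ds$ad_alt <- ad_alt; ds$pl <- pl
  ds
}

#' Pairwise relationship labels implied by a pedigree design
#'
#' Labels every unordered pair of individuals: `clone` (same clonal lineage),
#' `PO` (one is a genetic parent of the other), `FS` (same two parents,
#' including two offspring of the same selfing), `HS` (exactly one shared
#' parent), `unrelated` (no shared ancestry in the design), `other`
#' (remaining ancestry links, e.g. grandparent or avuncular).
#'
#' @param design A pedigree design tibble (see [simulate_cohort()]).
#' @return Tibble with columns `sample1`, `sample2`, `relation`.
#' @export
truth_relationships <- function(design) {
  ids <- design$id
  idx <- stats::setNames(seq_along(ids), ids)
  clone_root <- function(i) {
    while (design$type[i] == "clone") i <- idx[[design$parent1[i]]]
    i
  }
  roots <- vapply(seq_along(ids), clone_root, integer(1))
  gen_parents <- function(i) {
    i <- roots[i]
    switch(design$type[i],
           founder = integer(0),
           cross = roots[c(idx[[design$parent1[i]]], idx[[design$parent2[i]]])],
           self = rep(roots[idx[[design$parent1[i]]]], 2))
  }
  parents <- lapply(seq_along(ids), gen_parents)
  ancestors <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    anc <- parents[[i]]
    frontier <- anc
    while (length(frontier)) {
      nxt <- unique(unlist(parents[frontier]))
      nxt <- setdiff(nxt, anc)
      anc <- c(anc, nxt)
      frontier <- nxt
    }
    ancestors[[i]] <- unique(c(roots[i], anc))
  }
  pairs <- utils::combn(seq_along(ids), 2)
  rel <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ri <- roots[i]; rj <- roots[j]
    if (ri == rj) {
      rel[k] <- "clone"
    } else if (ri %in% parents[[j]] || rj %in% parents[[i]]) {
      rel[k] <- "PO"
    } else if (length(parents[[i]]) && length(parents[[j]]) &&
               identical(sort(parents[[i]]), sort(parents[[j]]))) {
      rel[k] <- "FS"
    } else if (length(intersect(parents[[i]], parents[[j]])) == 1) {
      rel[k] <- "HS"
    } else if (length(intersect(ancestors[[i]], ancestors[[j]]))) {
      rel[k] <- "other"
    } else {
      rel[k] <- "unrelated"
    }
  }
  tibble::tibble(sample1 = ids[pairs[1, ]], sample2 = ids[pairs[2, ]],
                 relation = rel)
}

#' Simulate a four-taxon cohort with optional donor gene flow
#'
#' Population allele frequencies follow the tree (((P1, P2), P3), O) by
#' successive Normal drift around the ancestral frequency (truncated to
#' [0, 1]); the outgroup is near-fixed for the ancestral (reference) allele.
#' Haplotypes are drawn site-wise from the population frequencies, after
#' which a fraction `f` of test-population (P2) haplotypes receive donor
#' tracts: within each tract the haplotype is resampled from the donor (P3)
#' frequencies. Ground truth records `f` and every tract.
#'
#' @param cfg A [sim_config()].
#' @param n_per_pop Named counts for `recipient` (P1), `test` (P2),
#'   `donor` (P3), `outgroup` (O).
#' @param drift Named standard deviations of the Normal drift: `split`
#'   (root to the (P1,P2) ancestor), `tip` (that ancestor to P1 and to P2),
#'   `donor` (root to P3). The default donor drift is large so that the donor
#'   carries many strongly differentiated (often fixed) alleles relative to
#'   the sister pair, the regime in which pattern-based admixture estimators
#'   are informative; with truncated Gaussian drift this requires a large
#'   standard deviation.
#' @param f Fraction of test-population haplotypes receiving donor tracts.
#' @param tracts Optional tibble (`chrom`, `start`, `end`, 0-based half-open)
#'   of tract intervals; by default tracts span the whole genome.
#' @param outgroup_derived Derived-allele frequency in the outgroup.
#' @param group_labels Named labels used for the four populations.
#' @param with_metadata Attach DP/AD/PL (default `TRUE`).
#' @return List with `dataset` and `truth` (`truth_set` carrying `f`,
#'   per-haplotype tract intervals and the true population frequencies).
#' @export
simulate_four_taxon <- function(cfg = sim_config(),
                                n_per_pop = c(recipient = 15, test = 15,
                                              donor = 15, outgroup = 4),
                                drift = c(split = 0.05, tip = 0.02, donor = 0.6),
                                f = 0, tracts = NULL, outgroup_derived = 0.01,
                                group_labels = c(recipient = "table",
                                                 test = "alpine_wine",
                                                 donor = "western_sylvestris",
                                                 outgroup = "outgroup"),
                                with_metadata = TRUE) {
  if (f < 0 || f > 1) stop("gene-flow fraction f must be in [0, 1]", call. = FALSE)
  chrom_lengths <- sim_chrom_lengths(cfg)
  mask <- simulate_mask(cfg, chrom_lengths)
  sites <- simulate_sites(cfg, chrom_lengths, mask)
  n <- nrow(sites)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  p_anc <- draw_founder_freqs(n, cfg)
  p12 <- clamp01(p_anc + stats::rnorm(n, 0, drift[["split"]]))
  pop_freq <- list(
    recipient = clamp01(p12 + stats::rnorm(n, 0, drift[["tip"]])),
    test = clamp01(p12 + stats::rnorm(n, 0, drift[["tip"]])),
    donor = clamp01(p_anc + stats::rnorm(n, 0, drift[["donor"]])),
    outgroup = rep(outgroup_derived, n))
  pops <- names(n_per_pop)
  prefix <- c(recipient = "T", test = "A", donor = "W", outgroup = "O")
  samples <- dplyr::bind_rows(lapply(pops, function(p) tibble::tibble(
    sample = sprintf("%s%02d", prefix[[p]], seq_len(n_per_pop[[p]])),
    group = group_labels[[p]], pop = p)))
  m <- nrow(samples)
  H1 <- matrix(NA_integer_, n, m); H2 <- H1
  for (p in pops) {
    cols <- which(samples$pop == p)
    H1[, cols] <- stats::rbinom(n * length(cols), 1, pop_freq[[p]])
    H2[, cols] <- stats::rbinom(n * length(cols), 1, pop_freq[[p]])
  }
  # donor tracts into the test population
  tract_truth <- tibble::tibble(sample = character(), hap = integer(),
                                chrom = character(), start = double(),
                                end = double())
  if (f > 0) {
    test_cols <- which(samples$pop == "test")
    hap_ids <- expand.grid(col = test_cols, hap = 1:2)
    n_sel <- round(f * nrow(hap_ids))
    sel <- hap_ids[sample.int(nrow(hap_ids), n_sel), , drop = FALSE]
    if (is.null(tracts)) {
      tracts_use <- tibble::tibble(chrom = names(chrom_lengths), start = 0,
                                   end = unname(chrom_lengths))
    } else {
      tracts_use <- tibble::as_tibble(tracts)
    }
    in_tract <- rep(FALSE, n)
    for (t in seq_len(nrow(tracts_use))) {
      in_tract <- in_tract | (sites$chrom == tracts_use$chrom[t] &
                                sites$pos - 1 >= tracts_use$start[t] &
                                sites$pos - 1 < tracts_use$end[t])
    }
    tsites <- which(in_tract)
    for (r in seq_len(nrow(sel))) {
      new_allele <- stats::rbinom(length(tsites), 1, pop_freq$donor[tsites])
      if (sel$hap[r] == 1) H1[tsites, sel$col[r]] <- new_allele
      else H2[tsites, sel$col[r]] <- new_allele
    }
    tract_truth <- dplyr::bind_rows(lapply(seq_len(nrow(sel)), function(r)
      dplyr::mutate(tracts_use, sample = samples$sample[sel$col[r]],
                    hap = sel$hap[r], .before = 1)))
  }
  gt <- H1 + H2
  hap1 <- H1; hap2 <- H2
  if (cfg$error_rate > 0) {
    err <- which(stats::runif(n * m) < cfg$error_rate)
    gt[err] <- (gt[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    hap1[err] <- NA_integer_; hap2[err] <- NA_integer_
  }
  ds <- genotype_dataset(sites, samples[, c("sample", "group")], gt,
                         hap1 = hap1, hap2 = hap2,
                         chrom_lengths = chrom_lengths, validate = FALSE)
  if (with_metadata) ds <- attach_call_metadata(ds, cfg)
  attr(ds, "mask") <- mask
  attr(ds, "sim_config") <- cfg
  truth <- structure(
    list(f = f, tracts = tract_truth, pop_freq = pop_freq,
         populations = samples, hap1 = H1, hap2 = H2, mask = mask),
    class = "truth_set")
  list(dataset = ds, truth = truth)
}

#' Impose a selective sweep on a phased dataset
#'
#' Inside `region`, each haplotype of each target-group sample is replaced by
#' one fixed swept haplotype with probability `swept_freq`; the rest of the
#' genome is untouched. Genotypes, phase and (if present) per-call metadata
#' at the region's sites are regenerated consistently.
#'
#' @param ds A phased [genotype_dataset()].
#' @param region List or one-row tibble with `chrom`, `start`, `end`
#'   (0-based half-open interval).
#' @param swept_freq Probability a target haplotype carries the swept
#'   haplotype; must be in (0.5, 1].
#' @param group Target group label(s) (default: all samples).
#' @return List with `dataset` and `truth` (region, swept frequency, swept
#'   haplotype alleles, replaced haplotypes).
#' @export
simulate_sweep <- function(ds, region, swept_freq, group = NULL) {
  stopifnot(has_phase(ds))
  if (swept_freq <= 0.5 || swept_freq > 1) {
    stop("swept_freq must be in (0.5, 1]", call. = FALSE)
  }
  idx <- which(ds$sites$chrom == region$chrom &
                 ds$sites$pos - 1 >= region$start &
                 ds$sites$pos - 1 < region$end)
  if (!length(idx)) stop("region overlaps no sites", call. = FALSE)
  target <- if (is.null(group)) ds$samples$sample else group_samples(ds, group)
  cols <- match(target, ds$samples$sample)
  swept <- ds$hap1[idx, cols[1]]
  if (anyNA(swept)) {  # fall back to a complete haplotype in the region
    swept[is.na(swept)] <- ds$hap2[idx, cols[1]][is.na(swept)]
    swept[is.na(swept)] <- 0L
  }
  hap_grid <- expand.grid(col = cols, hap = 1:2)
  replaced <- stats::runif(nrow(hap_grid)) < swept_freq
  for (r in which(replaced)) {
    if (hap_grid$hap[r] == 1) ds$hap1[idx, hap_grid$col[r]] <- swept
    else ds$hap2[idx, hap_grid$col[r]] <- swept
  }
  aff <- unique(hap_grid$col[replaced])
  newgt <- ds$hap1[idx, aff, drop = FALSE] + ds$hap2[idx, aff, drop = FALSE]
  oldgt <- ds$gt[idx, aff, drop = FALSE]
  newgt[is.na(newgt)] <- oldgt[is.na(newgt)]  # keep calls whose phase is unknown
  ds$gt[idx, aff] <- newgt
  cfg <- attr(ds, "sim_config")
  if (has_metadata(ds) && !is.null(cfg)) {
    sub <- subset_sites(ds, idx)
    sub <- attach_call_metadata(sub, cfg)
    ds$dp[idx, ] <- sub$dp; ds$ad_ref[idx, ] <- sub$ad_ref
    ds$ad_alt[idx, ] <- sub$ad_alt; ds$pl[idx, , ] <- sub$pl
  }
  truth <- structure(
    list(region = tibble::as_tibble(region[c("chrom", "start", "end")]),
         swept_freq = swept_freq, swept_hap = swept,
         replaced = tibble::tibble(
           sample = ds$samples$sample[hap_grid$col[replaced]],
           hap = hap_grid$hap[replaced])),
    class = "truth_set")
  list(dataset = ds, truth = truth)
}

#' Simulate a regional haplotype panel
#'
#' Builds a small phased single-chromosome dataset from a set of distinct
#' planted haplotypes and a diplotype design, for exercising regional
#' haplotype inference against known truth.
#'
#' @param n_sites Number of variant sites in the region.
#' @param n_hap Number of distinct haplotypes to plant.
#' @param diplotypes Tibble with columns `sample`, `hap1`, `hap2` (haplotype
#'   indices in `1:n_hap`). Default: one accession homozygous for haplotype 1
#'   (the reference) and one heterozygous `1/k` accession per other haplotype.
#' @return List with `dataset`, `haplotypes` (sites x n_hap matrix) and
#'   `diplotypes`.
#' @export
simulate_haplotype_panel <- function(n_sites = 40, n_hap = 8, diplotypes = NULL) {
  repeat {
    H <- matrix(stats::rbinom(n_sites * n_hap, 1, 0.5), n_sites, n_hap)
    if (!anyDuplicated(t(H)) && !all(H[, 1] == 0)) break
  }
  if (is.null(diplotypes)) {
    diplotypes <- dplyr::bind_rows(
      tibble::tibble(sample = "ACC01", hap1 = 1L, hap2 = 1L),
      tibble::tibble(sample = sprintf("ACC%02d", seq_len(n_hap - 1) + 1),
                     hap1 = 1L, hap2 = seq_len(n_hap - 1) + 1L))
  }
  hap1 <- H[, diplotypes$hap1, drop = FALSE]
  hap2 <- H[, diplotypes$hap2, drop = FALSE]
  sites <- tibble::tibble(
    chrom = "chr01", pos = seq_len(n_sites) * 100L,
    ref = "A", alt = "T", qual = 1000, masked = FALSE)
  samples <- tibble::tibble(sample = diplotypes$sample, group = "cultivated")
  ds <- genotype_dataset(sites, samples, hap1 + hap2, hap1 = hap1, hap2 = hap2,
                         chrom_lengths = c(chr01 = n_sites * 100 + 100))
  list(dataset = ds, haplotypes = H, diplotypes = diplotypes)
}

#' Simulate replicated allele-specific read counts
#'
#' @param n_genes Number of genes.
#' @param n_rep Replicates per gene.
#' @param depth Allele-informative reads per replicate.
#' @param ratio True reference-allele fraction (scalar or per gene).
#' @param sample Sample label.
#' @return Tibble with columns `gene`, `sample`, `replicate`, `ref_count`,
#'   `alt_count`, `fpkm`.
#' @export
simulate_ase_counts <- function(n_genes = 500, n_rep = 2, depth = 200,
                                ratio = 0.5, sample = "S1") {
  ratio <- rep(ratio, length.out = n_genes)
  fpkm <- round(stats::rlnorm(n_genes, meanlog = 3, sdlog = 1), 3)
  out <- tidyr::expand_grid(gene = sprintf("gene%04d", seq_len(n_genes)),
                            replicate = seq_len(n_rep))
  out$sample <- sample
  out$ref_count <- stats::rbinom(nrow(out), depth,
                                 rep(ratio, each = n_rep))
  out$alt_count <- depth - out$ref_count
  out$fpkm <- rep(fpkm, each = n_rep)
  out[, c("gene", "sample", "replicate", "ref_count", "alt_count", "fpkm")]
}
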