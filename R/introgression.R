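#' Outgroup polarization of segregating sites
#'
#' Determines the ancestral allele at each site as the single allele carried
#' by the outgroup samples; sites where the outgroup is heterozygous,
#' segregating, or entirely uncalled are non-polarizable. When a set of
#' additional non-target species is supplied, a site is flagged
#' trans-specific if both target alleles are also observed among those
#' species (polymorphism predating speciation). Per-group derived-allele
#' frequencies are computed for every group in the dataset.
#'
#' @param ds A [genotype_dataset()].
#' @param outgroup_samples Sample ids of the outgroup.
#' @param other_species Optional sample ids of further non-target species
#'   used for the trans-specific flag.
#' @param groups Group labels for which derived frequencies are computed
#'   (default: all groups).
#' @return An object of class `polarized_sites`: list with `sites` (tibble:
#'   `chrom`, `pos`, `ancestral`, `derived`, `polarizable`, `trans_specific`)
#'   and `freqs` (matrix of derived-allele frequencies, sites x groups;
#'   `NA` at non-polarizable sites).
#' @export
polarize <- function(ds, outgroup_samples, other_species = NULL,
                     groups = unique(ds$samples$group)) {
  cols <- match(outgroup_samples, ds$samples$sample)
  if (anyNA(cols)) {
    stop("unknown outgroup sample(s): ",
         paste(outgroup_samples[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  og <- ds$gt[, cols, drop = FALSE]
  n_called <- rowSums(!is.na(og))
  if (all(n_called == 0)) {
    stop("no outgroup calls at any site; cannot polarize", call. = FALSE)
  }
  has_ref <- rowSums(og < 2, na.rm = TRUE) > 0   # hom-ref or het carries ref
  has_alt <- rowSums(og > 0, na.rm = TRUE) > 0
  polarizable <- n_called > 0 & xor(has_ref, has_alt)
  ancestral <- ifelse(!polarizable, NA_character_,
                      ifelse(has_alt, ds$sites$alt, ds$sites$ref))
  derived <- ifelse(!polarizable, NA_character_,
                    ifelse(has_alt, ds$sites$ref, ds$sites$alt))
  trans_specific <- rep(NA, n_sites(ds))
  if (!is.null(other_species)) {
    oc <- match(other_species, ds$samples$sample)
    sp <- ds$gt[, oc, drop = FALSE]
    trans_specific <- rowSums(sp < 2, na.rm = TRUE) > 0 &
      rowSums(sp > 0, na.rm = TRUE) > 0
  }
  alt_freq <- group_freqs(ds, groups)
  freqs <- alt_freq
  flip <- polarizable & ancestral == ds$sites$alt
  freqs[flip, ] <- 1 - freqs[flip, ]
  freqs[!polarizable, ] <- NA_real_
  structure(
    list(sites = tibble::tibble(
      chrom = ds$sites$chrom, pos = ds$sites$pos,
      ancestral = ancestral, derived = derived,
      polarizable = polarizable, trans_specific = trans_specific,
      masked = ds$sites$masked),
      freqs = freqs),
    class = "polarized_sites")
}

#' @export
print.polarized_sites <- function(x, ...) {
  cat(sprintf("<polarized_sites> %s sites, %s polarizable (%.1f%%)",
              format(nrow(x$sites), big.mark = ","),
              format(sum(x$sites$polarizable), big.mark = ","),
              100 * mean(x$sites$polarizable)))
  if (!all(is.na(x$sites$trans_specific))) {
    cat(sprintf(", %.1f%% trans-specific",
                100 * mean(x$sites$trans_specific, na.rm = TRUE)))
  }
  cat("\n  groups:", paste(colnames(x$freqs), collapse = ", "), "\n")
  invisible(x)
}

#' Unfolded site frequency spectrum
#'
#' Histogram of derived-allele counts in a target group over polarizable
#' sites at which every group sample is called.
#'
#' @param pol A [polarize()] result.
#' @param ds The same [genotype_dataset()].
#' @param group Target group label(s).
#' @return Tibble with `k` (derived copies, `0..2n`) and `n_sites`.
#' @export
unfolded_sfs <- function(pol, ds, group) {
  cols <- which(ds$samples$group %in% group)
  sub <- ds$gt[, cols, drop = FALSE]
  full <- rowSums(is.na(sub)) == 0 & pol$sites$polarizable
  alt_count <- rowSums(sub[full, , drop = FALSE])
  anc_is_alt <- pol$sites$ancestral[full] == ds$sites$alt[full]
  kk <- ifelse(anc_is_alt, 2 * length(cols) - alt_count, alt_count)
  counts <- tabulate(kk + 1, nbins = 2 * length(cols) + 1)
  tibble::tibble(k = 0:(2 * length(cols)), n_sites = counts)
}

site_pattern_terms <- function(p1, p2, p3, po) {
  list(abba = (1 - p1) * p2 * p3 * (1 - po),
       baba = p1 * (1 - p2) * p3 * (1 - po))
}

#' Windowed ABBA-BABA D and adjusted f_d scan
#'
#' Frequency-based site patterns `ABBA = (1-p1) p2 p3 (1-pO)` and
#' `BABA = p1 (1-p2) p3 (1-pO)` are summed per window;
#' `D = sum(ABBA-BABA) / sum(ABBA+BABA)`. The admixture-fraction estimator
#' `f_d` divides the same numerator by the value it would take if the donor
#' slot were occupied, site by site, by whichever of P2/P3 has the higher
#' derived frequency; windows with `D <= 0` report `f_d` as undefined (set
#' `fd_zero = TRUE` to emit 0 instead, for plotting). The genome-wide D is
#' accompanied by a block-jackknife standard error and Z score over blocks of
#' `block_snps` consecutive informative sites, and a genome-wide f_d is
#' computed from the genome totals.
#'
#' @param pol A [polarize()] result (or compatible list with `sites`,
#'   `freqs`).
#' @param p1,p2,p3,po Group labels for recipient-sister (P1), test (P2),
#'   donor (P3) and outgroup (O), as columns of `pol$freqs`.
#' @param ws A sliding [window_set][make_windows()] (any window set works).
#' @param block_snps Jackknife block size in informative sites.
#' @param fd_zero Emit 0 instead of `NA` for windows with `D <= 0`.
#' @return An `introgression_scan`: list with `windows` tibble (`abba`,
#'   `baba`, `D`, `fd`, `n_sites` per window) and `genome` (one-row tibble
#'   with `D`, `se`, `z`, `n_blocks`, `fd`, `n_sites`).
#' @export
d_fd_scan <- function(pol, p1, p2, p3, po, ws, block_snps = 300,
                      fd_zero = FALSE) {
  fr <- pol$freqs
  need <- c(p1, p2, p3, po)
  miss <- setdiff(need, colnames(fr))
  if (length(miss)) {
    stop("group(s) without frequencies: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  q1 <- fr[, p1]; q2 <- fr[, p2]; q3 <- fr[, p3]; qo <- fr[, po]
  use <- !is.na(q1) & !is.na(q2) & !is.na(q3) & !is.na(qo) &
    pol$sites$polarizable
  pat <- site_pattern_terms(q1, q2, q3, qo)
  qd <- pmax(q2, q3)
  pat_d <- site_pattern_terms(q1, qd, qd, qo)
  num <- ifelse(use, pat$abba - pat$baba, NA_real_)
  den <- ifelse(use, pat$abba + pat$baba, NA_real_)
  den_d <- ifelse(use, pat_d$abba - pat_d$baba, NA_real_)
  # windowed sums
  site_ds <- list(sites = pol$sites)  # assign_sites needs $sites only
  class(site_ds) <- "genotype_dataset"
  asg <- assign_sites(site_ds, ws)
  asg <- asg[use[asg$site], ]
  grp <- factor(asg$window, levels = ws$index)
  wsum <- function(x) {
    out <- rep(0, nrow(ws))
    r <- rowsum(x[asg$site], grp)
    out[match(rownames(r), as.character(ws$index))] <- r[, 1]
    out
  }
  sum_num <- wsum(num); sum_den <- wsum(den); sum_dend <- wsum(den_d)
  n_sites_w <- wsum(rep(1, length(num)))
  D <- ifelse(sum_den > 0, sum_num / sum_den, NA_real_)
  fd <- ifelse(!is.na(D) & D > 0 & sum_dend != 0, sum_num / sum_dend,
               NA_real_)
  if (fd_zero) fd[!is.na(D) & D <= 0] <- 0
  windows <- dplyr::mutate(tibble::as_tibble(ws),
                           n_sites = n_sites_w, abba = wsum(pat$abba),
                           baba = wsum(pat$baba), D = D, fd = fd)
  # genome-wide D with block jackknife over informative sites
  iu <- which(use)
  genome <- genome_d_jackknife(num[iu], den[iu], block_snps)
  genome$fd <- sum(num[iu]) / sum(den_d[iu])
  genome$n_sites <- length(iu)
  structure(list(windows = windows, genome = tibble::as_tibble(genome)),
            class = "introgression_scan")
}

genome_d_jackknife <- function(num, den, block_snps) {
  tn <- sum(num); td <- sum(den)
  D <- if (td > 0) tn / td else NA_real_
  blk <- ceiling(seq_along(num) / block_snps)
  B <- max(blk)
  if (B < 2 || is.na(D)) {
    return(list(D = D, se = NA_real_, z = NA_real_, n_blocks = B))
  }
  bn <- rowsum(num, blk)[, 1]
  bd <- rowsum(den, blk)[, 1]
  loo <- (tn - bn) / (td - bd)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(D = D, se = se, z = D / se, n_blocks = B)
}

#' @export
print.introgression_scan <- function(x, ...) {
  g <- x$genome
  cat(sprintf("<introgression_scan> %d windows; genome D = %.4f (SE %.4f, Z %.2f, %d blocks); genome f_d = %.4f\n",
              nrow(x$windows), g$D, g$se, g$z, g$n_blocks, g$fd))
  invisible(x)
}

#' @export
tidy.introgression_scan <- function(x, ...) x$windows

#' @export
glance.introgression_scan <- function(x, ...) x$genome

#' Three-population test
#'
#' `f3(target; A, B) = mean over sites of (pT - pA)(pT - pB)` with a block
#' jackknife standard error; a significantly negative Z indicates the target
#' cannot be a simple drifted descendant of either source, i.e. admixture.
#'
#' @param pol A [polarize()] result.
#' @param target,source_a,source_b Group labels (must be distinct).
#' @param block_snps Jackknife block size in sites.
#' @return One-row tibble: `f3`, `se`, `z`, `n_sites`, `n_blocks`. With a
#'   single block the SE and Z are `NA`.
#' @export
f3_test <- function(pol, target, source_a, source_b, block_snps = 300) {
  if (anyDuplicated(c(target, source_a, source_b))) {
    stop("target and sources must be distinct groups", call. = FALSE)
  }
  fr <- pol$freqs
  pt <- fr[, target]; pa <- fr[, source_a]; pb <- fr[, source_b]
  use <- !is.na(pt) & !is.na(pa) & !is.na(pb)
  x <- (pt - pa)[use] * (pt - pb)[use]
  f3 <- mean(x)
  blk <- ceiling(seq_along(x) / block_snps)
  B <- max(blk)
  if (B < 2) {
    return(tibble::tibble(f3 = f3, se = NA_real_, z = NA_real_,
                          n_sites = length(x), n_blocks = B))
  }
  bs <- rowsum(x, blk)[, 1]
  bl <- rowsum(rep(1, length(x)), blk)[, 1]
  loo <- (sum(x) - bs) / (length(x) - bl)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  tibble::tibble(f3 = f3, se = se, z = f3 / se, n_sites = length(x),
                 n_blocks = B)
}

#' Nei's D_A distance between two frequency vectors
#'
#' `D_A = 1 - (1/L) * sum over sites of [sqrt(x y) + sqrt((1-x)(1-y))]`.
#'
#' @param x,y Allele-frequency vectors (same allele orientation).
#' @return A number in [0, 1]; `NA` if no shared defined sites.
#' @export
da_distance <- function(x, y) {
  use <- !is.na(x) & !is.na(y)
  if (!any(use)) return(NA_real_)
  1 - mean(sqrt(x[use] * y[use]) + sqrt((1 - x[use]) * (1 - y[use])))
}

#' Windowed D_A topology scan
#'
#' Per window, computes Nei's D_A distance between the focal group and each
#' comparison group (the donor and every other group) from sample allele
#' frequencies, and flags the window when the focal group is nearer to the
#' donor than to any other comparison group.
#'
#' @param ds A [genotype_dataset()].
#' @param focal Focal group label.
#' @param donor Donor group label.
#' @param others Other comparison group labels (at least one).
#' @param ws A [window_set][make_windows()].
#' @param include_partial Include partial windows (default `FALSE`).
#' @return A tibble of class `topology_scan`: window columns plus
#'   `da_donor`, `da_other_min`, `flagged`; attributes `genome_fraction`
#'   (length-weighted flagged fraction) and `n_empty` (windows without
#'   usable sites, skipped).
#' @export
da_topology_scan <- function(ds, focal, donor, others, ws,
                             include_partial = FALSE) {
  if (length(others) < 1) stop("need at least one other group", call. = FALSE)
  wtab <- if (include_partial) ws else ws[!ws$partial, ]
  fr <- group_freqs(ds, c(focal, donor, others))
  asg <- assign_sites(ds, ws)
  asg <- asg[asg$window %in% wtab$index, ]
  split_sites <- split(asg$site, asg$window)
  rows <- purrr::map(seq_len(nrow(wtab)), function(i) {
    s <- split_sites[[as.character(wtab$index[i])]]
    if (is.null(s)) {
      return(tibble::tibble(da_donor = NA_real_, da_other_min = NA_real_,
                            n_sites = 0L))
    }
    dd <- da_distance(fr[s, focal], fr[s, donor])
    doth <- vapply(others, function(g) da_distance(fr[s, focal], fr[s, g]),
                   numeric(1))
    tibble::tibble(da_donor = dd,
                   da_other_min = if (all(is.na(doth))) NA_real_ else
                     min(doth, na.rm = TRUE),
                   n_sites = length(s))
  })
  out <- dplyr::bind_cols(tibble::as_tibble(wtab), dplyr::bind_rows(rows))
  out$flagged <- !is.na(out$da_donor) & !is.na(out$da_other_min) &
    out$da_donor < out$da_other_min
  span <- out$end - out$start
  attr(out, "genome_fraction") <- sum(span[out$flagged]) / sum(span)
  attr(out, "n_empty") <- sum(out$n_sites == 0)
  class(out) <- c("topology_scan", class(out))
  out
}
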