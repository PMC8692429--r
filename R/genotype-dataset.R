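#' Diploid genotype cohort
#'
#' `genotype_dataset()` builds the central container used by every scan in the
#' package: a sites-by-samples table of biallelic SNP calls with optional
#' per-call sequencing metadata (read depth `DP`, allele depths `AD`,
#' normalized Phred-scaled genotype likelihoods `PL`), per-site quality
#' (`QUAL`), a repeat-mask flag per site, and an optional truth/consistent
#' phasing of each call.
#'
#' Genotypes are stored as alternate-allele dosage: 0 (hom-ref), 1 (het),
#' 2 (hom-alt), `NA` (missing). Sites must be biallelic single-nucleotide
#' variants with strictly increasing positions within each chromosome
#' (1-based, VCF convention). Allele depths must never exceed `DP`, and where
#' `PL` is present exactly one likelihood per called genotype must be 0;
#' datasets violating these invariants are rejected.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and optionally `qual` (numeric) and `masked` (logical, site falls in
#'   repetitive DNA).
#' @param samples Tibble with columns `sample` and `group` (free-vocabulary
#'   population label, e.g. `"western_sylvestris"`, `"table"`, `"outgroup"`).
#' @param gt Integer matrix (sites x samples) of alternate-allele dosages.
#' @param dp,ad_ref,ad_alt Optional integer matrices (sites x samples) of read
#'   depth and per-allele depths.
#' @param pl Optional integer array (sites x samples x 3) of genotype
#'   likelihoods ordered hom-ref, het, hom-alt.
#' @param hap1,hap2 Optional integer matrices (sites x samples) of phased
#'   alleles (0 = ref, 1 = alt); `NA` where the phase is unknown.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param validate Set to `FALSE` to skip invariant checks (internal use).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(sites, samples, gt, dp = NULL, ad_ref = NULL,
                             ad_alt = NULL, pl = NULL, hap1 = NULL, hap2 = NULL,
                             chrom_lengths = NULL, validate = TRUE) {
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    stop("`sites` needs columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (is.null(sites$qual)) sites$qual <- NA_real_
  if (is.null(sites$masked)) sites$masked <- FALSE
  if (!all(c("sample", "group") %in% names(samples))) {
    stop("`samples` needs columns sample, group", call. = FALSE)
  }
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  colnames(gt) <- samples$sample
  name_cols <- function(m) {
    if (!is.null(m)) colnames(m) <- samples$sample
    m
  }
  dp <- name_cols(dp); ad_ref <- name_cols(ad_ref); ad_alt <- name_cols(ad_alt)
  hap1 <- name_cols(hap1); hap2 <- name_cols(hap2)
  if (!is.null(pl)) dimnames(pl) <- list(NULL, samples$sample, NULL)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  ds <- structure(
    list(sites = sites, samples = samples, gt = gt, dp = dp,
         ad_ref = ad_ref, ad_alt = ad_alt, pl = pl,
         hap1 = hap1, hap2 = hap2, chrom_lengths = chrom_lengths),
    class = "genotype_dataset"
  )
  if (validate) validate_genotype_dataset(ds)
  ds
}

validate_genotype_dataset <- function(ds) {
  sites <- ds$sites
  if (nrow(sites) != nrow(ds$gt) || nrow(ds$samples) != ncol(ds$gt)) {
    stop("genotype matrix dimensions do not match sites/samples", call. = FALSE)
  }
  bad_allele <- !(sites$ref %in% c("A", "C", "G", "T")) |
    !(sites$alt %in% c("A", "C", "G", "T")) | sites$ref == sites$alt
  if (any(bad_allele)) {
    stop("non-biallelic or non-SNP alleles at site(s) ",
         paste(utils::head(which(bad_allele), 5), collapse = ", "), call. = FALSE)
  }
  ooo <- unlist(tapply(sites$pos, factor(sites$chrom, unique(sites$chrom)),
                       function(p) diff(p) <= 0), use.names = FALSE)
  if (any(ooo)) {
    stop("positions not strictly increasing within chromosome", call. = FALSE)
  }
  if (!all(ds$gt %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (!is.null(ds$dp) && !is.null(ds$ad_ref)) {
    over <- which(ds$ad_ref + ds$ad_alt > ds$dp)
    if (length(over)) {
      stop("AD components exceed DP at ", length(over), " call(s); rejecting dataset",
           call. = FALSE)
    }
  }
  if (!is.null(ds$pl)) {
    called <- !is.na(ds$gt)
    nz <- (ds$pl[, , 1] == 0L) + (ds$pl[, , 2] == 0L) + (ds$pl[, , 3] == 0L)
    bad <- which(called & (is.na(nz) | nz != 1L))
    if (length(bad)) {
      stop("PL must have exactly one zero entry per called genotype (",
           length(bad), " violations); rejecting dataset", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %s sites x %s samples (%d chromosome%s)\n",
              format(n_sites(x), big.mark = ","),
              n_samples(x), length(x$chrom_lengths),
              if (length(x$chrom_lengths) == 1) "" else "s"))
  grp <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf("  masked sites: %s; metadata: %s; phase: %s\n",
              format(sum(x$sites$masked), big.mark = ","),
              if (has_metadata(x)) "DP/AD/PL" else "none",
              if (has_phase(x)) "present" else "absent"))
  invisible(x)
}

#' Dataset dimensions and accessors
#'
#' @param ds A [genotype_dataset()].
#' @return `n_sites()`/`n_samples()` return integers; `gt_dosage()` the
#'   dosage matrix; `group_samples()` the sample ids carrying a group label.
#' @export
n_sites <- function(ds) nrow(ds$sites)

#' @rdname n_sites
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' @rdname n_sites
#' @export
gt_dosage <- function(ds) ds$gt

#' @rdname n_sites
#' @param group One or more group labels.
#' @export
group_samples <- function(ds, group) ds$samples$sample[ds$samples$group %in% group]

#' @rdname n_sites
#' @export
has_metadata <- function(ds) {
  !is.null(ds$dp) && !is.null(ds$ad_ref) && !is.null(ds$pl)
}

#' @rdname n_sites
#' @export
has_phase <- function(ds) !is.null(ds$hap1) && !is.null(ds$hap2)

#' Subset a dataset by site or sample
#'
#' @param ds A [genotype_dataset()].
#' @param keep Logical or integer index over sites (`subset_sites`) or a
#'   character vector of sample ids (`subset_samples`).
#' @return A new `genotype_dataset`.
#' @export
subset_sites <- function(ds, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  pick <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  genotype_dataset(ds$sites[idx, ], ds$samples, pick(ds$gt),
                   dp = pick(ds$dp), ad_ref = pick(ds$ad_ref), ad_alt = pick(ds$ad_alt),
                   pl = if (is.null(ds$pl)) NULL else ds$pl[idx, , , drop = FALSE],
                   hap1 = pick(ds$hap1), hap2 = pick(ds$hap2),
                   chrom_lengths = ds$chrom_lengths, validate = FALSE)
}

#' @rdname subset_sites
#' @export
subset_samples <- function(ds, keep) {
  idx <- match(keep, ds$samples$sample)
  if (anyNA(idx)) {
    stop("unknown sample(s): ", paste(keep[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  pick <- function(m) if (is.null(m)) NULL else m[, idx, drop = FALSE]
  genotype_dataset(ds$sites, ds$samples[idx, ], pick(ds$gt),
                   dp = pick(ds$dp), ad_ref = pick(ds$ad_ref), ad_alt = pick(ds$ad_alt),
                   pl = if (is.null(ds$pl)) NULL else ds$pl[, idx, , drop = FALSE],
                   hap1 = pick(ds$hap1), hap2 = pick(ds$hap2),
                   chrom_lengths = ds$chrom_lengths, validate = FALSE)
}

#' Per-group alternate or derived allele frequencies
#'
#' Sample allele frequency of the alternate allele among called haplotypes,
#' computed per site for each listed group.
#'
#' @param ds A [genotype_dataset()].
#' @param groups Character vector of group labels (default: all groups).
#' @return Numeric matrix, sites x groups; `NaN` where no calls.
#' @export
group_freqs <- function(ds, groups = unique(ds$samples$group)) {
  out <- matrix(NA_real_, n_sites(ds), length(groups),
                dimnames = list(NULL, groups))
  for (g in groups) {
    cols <- which(ds$samples$group == g)
    sub <- ds$gt[, cols, drop = FALSE]
    called <- rowSums(!is.na(sub))
    out[, g] <- rowSums(sub, na.rm = TRUE) / (2 * called)
  }
  out
}

#' @export
tidy.genotype_dataset <- function(x, ...) {
  long <- tibble::tibble(
    site = rep(seq_len(n_sites(x)), times = n_samples(x)),
    chrom = rep(x$sites$chrom, times = n_samples(x)),
    pos = rep(x$sites$pos, times = n_samples(x)),
    sample = rep(x$samples$sample, each = n_sites(x)),
    gt = as.vector(x$gt)
  )
  if (!is.null(x$dp)) long$dp <- as.vector(x$dp)
  if (!is.null(x$ad_ref)) {
    long$ad_ref <- as.vector(x$ad_ref)
    long$ad_alt <- as.vector(x$ad_alt)
  }
  long
}

#' @export
glance.genotype_dataset <- function(x, ...) {
  tibble::tibble(
    n_sites = n_sites(x), n_samples = n_samples(x),
    n_chrom = length(x$chrom_lengths),
    n_masked = sum(x$sites$masked),
    missing_rate = mean(is.na(x$gt)),
    has_metadata = has_metadata(x), has_phase = has_phase(x)
  )
}
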