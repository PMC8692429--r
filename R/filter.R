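#' Genotype-filter configuration
#'
#' Thresholds of the multi-rule call- and site-retention cascade. Defaults
#' follow the reference pipeline: variant quality above 50 (Phred), at least
#' 5 reads per call, depth within 0.5-1.5x the sample's modal coverage (lower
#' bound relaxed to 0.25x for homozygous calls; upper bound relaxed to 2.5x
#' when the site already passes in at least 5 other samples), heterozygous
#' reference-allele balance within [0.25, 0.75], homozygous calls with an
#' assigned PL of 0 and minimum non-zero PL above 10, per-called-allele
#' AD/DP above 0.05, sites kept only when more than 50% of samples pass and
#' at least one passing sample carries the alternate allele.
#'
#' @param qual_min Minimum site QUAL (strict `>`).
#' @param dp_min Minimum reads per call.
#' @param band_low,band_high Depth band as multiples of modal coverage.
#' @param hom_band_low Relaxed lower multiple for homozygous calls.
#' @param relaxed_high Relaxed upper multiple (cross-sample relaxation).
#' @param relax_support Other samples that must pass strictly for the
#'   relaxation to apply.
#' @param het_balance Length-2 allele-balance band for heterozygous calls.
#' @param hom_pl_min Minimum non-zero PL for homozygous calls (strict `>`).
#' @param ad_dp_min Minimum called-allele depth fraction (strict `>`).
#' @param site_retention Passing-sample fraction a site must exceed
#'   (strict `>`).
#' @param min_carriers Minimum passing samples carrying the alternate allele.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qual_min = 50, dp_min = 5, band_low = 0.5,
                          band_high = 1.5, hom_band_low = 0.25,
                          relaxed_high = 2.5, relax_support = 5,
                          het_balance = c(0.25, 0.75), hom_pl_min = 10,
                          ad_dp_min = 0.05, site_retention = 0.5,
                          min_carriers = 1) {
  if (relaxed_high < band_high) {
    stop("relaxed_high must be >= band_high", call. = FALSE)
  }
  stopifnot(band_low > 0, band_low < band_high,
            length(het_balance) == 2, het_balance[1] < het_balance[2])
  structure(
    list(qual_min = qual_min, dp_min = dp_min, band_low = band_low,
         band_high = band_high, hom_band_low = hom_band_low,
         relaxed_high = relaxed_high, relax_support = relax_support,
         het_balance = het_balance, hom_pl_min = hom_pl_min,
         ad_dp_min = ad_dp_min, site_retention = site_retention,
         min_carriers = min_carriers),
    class = "filter_config")
}

#' Modal coverage of a sample
#'
#' Mode of the integer read-depth histogram over all calls of the sample;
#' ties are broken toward the smaller depth.
#'
#' @param ds A [genotype_dataset()] with DP.
#' @param sample Sample id (or all samples when `NULL`).
#' @return Named numeric vector of modal coverages.
#' @export
modal_coverage <- function(ds, sample = NULL) {
  if (is.null(ds$dp)) stop("dataset has no DP field", call. = FALSE)
  ids <- if (is.null(sample)) ds$samples$sample else sample
  out <- vapply(ids, function(s) {
    dp <- ds$dp[, match(s, ds$samples$sample)]
    dp <- dp[!is.na(dp)]
    if (!length(dp)) stop("all DP missing for sample ", s, call. = FALSE)
    tab <- table(dp)
    vals <- as.integer(names(tab))
    vals[which.max(tab)]  # table is sorted by value; first max = smallest
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Apply the call-level filter cascade
#'
#' Two-pass evaluation. Pass 1 applies every rule with the strict coverage
#' band (homozygous calls use the relaxed lower bound). Pass 2 re-admits
#' calls that failed only the upper coverage bound, lie within the relaxed
#' upper bound, and sit at sites where at least `relax_support` other
#' samples passed pass 1. Rules are evaluated in a fixed order (missing
#' call, QUAL, minimum depth, coverage band, heterozygous allele balance,
#' homozygous PL, allele-depth fraction) and the first failing rule is
#' recorded per call.
#'
#' @param ds A [genotype_dataset()] with DP/AD/PL/QUAL.
#' @param cfg A [filter_config()].
#' @param modal Optional named per-sample modal coverages. By default they are
#'   taken from the dataset's `modal_coverage` attribute (set by
#'   [filter_cohort()], so the estimate from the unfiltered call set travels
#'   with its output) or estimated with [modal_coverage()].
#' @return A `filter_report`: list with logical matrix `pass`, character
#'   matrix `first_fail`, pass-1 matrix `pass1`, per-sample `modal`
#'   coverages, the number of re-admitted calls, and per-rule failure counts.
#' @export
apply_call_filters <- function(ds, cfg = filter_config(), modal = NULL) {
  if (!has_metadata(ds)) {
    stop("call filtering requires DP, AD and PL; this dataset lacks them",
         call. = FALSE)
  }
  if (all(is.na(ds$sites$qual))) {
    stop("call filtering requires site QUAL", call. = FALSE)
  }
  n <- n_sites(ds); m <- n_samples(ds)
  modal <- modal %||% attr(ds, "modal_coverage") %||% modal_coverage(ds)
  modal <- modal[ds$samples$sample]
  modal_m <- matrix(rep(modal, each = n), n, m)
  gt <- ds$gt; dp <- ds$dp
  het <- !is.na(gt) & gt == 1L
  hom <- !is.na(gt) & gt != 1L
  qual_ok <- matrix(!is.na(ds$sites$qual) & ds$sites$qual > cfg$qual_min, n, m)
  dp_ok <- !is.na(dp) & dp >= cfg$dp_min
  lower <- ifelse(hom, cfg$hom_band_low, cfg$band_low) * modal_m
  band_low_ok <- !is.na(dp) & dp >= lower
  band_high_ok <- !is.na(dp) & dp <= cfg$band_high * modal_m
  relaxed_high_ok <- !is.na(dp) & dp <= cfg$relaxed_high * modal_m
  ref_frac <- ds$ad_ref / (ds$ad_ref + ds$ad_alt)
  balance_ok <- !het |
    (!is.na(ref_frac) & ref_frac >= cfg$het_balance[1] &
       ref_frac <= cfg$het_balance[2])
  pl_assigned <- matrix(NA_integer_, n, m)
  idx0 <- which(!is.na(gt) & gt == 0L); idx2 <- which(!is.na(gt) & gt == 2L)
  pl_assigned[idx0] <- ds$pl[, , 1][idx0]
  pl_assigned[idx2] <- ds$pl[, , 3][idx2]
  min_nz <- function(a, b) {
    x <- ifelse(a == 0L, Inf, a)
    y <- ifelse(b == 0L, Inf, b)
    pmin(x, y)
  }
  pl_min_other <- matrix(NA_real_, n, m)
  pl_min_other[idx0] <- min_nz(ds$pl[, , 2], ds$pl[, , 3])[idx0]
  pl_min_other[idx2] <- min_nz(ds$pl[, , 1], ds$pl[, , 2])[idx2]
  pl_ok <- !hom |
    (!is.na(pl_assigned) & pl_assigned == 0L &
       !is.na(pl_min_other) & pl_min_other > cfg$hom_pl_min)
  # AD/DP for every called allele: hom -> the called allele; het -> both
  frac_ref <- ds$ad_ref / dp
  frac_alt <- ds$ad_alt / dp
  ad_dp_ok <- !is.na(gt) & !is.na(dp) & dp > 0 &
    ifelse(gt == 0L, frac_ref > cfg$ad_dp_min,
           ifelse(gt == 2L, frac_alt > cfg$ad_dp_min,
                  frac_ref > cfg$ad_dp_min & frac_alt > cfg$ad_dp_min))
  called <- !is.na(gt)
  pass1 <- called & qual_ok & dp_ok & band_low_ok & band_high_ok &
    balance_ok & pl_ok & ad_dp_ok
  # pass 2: re-admit calls failing only the strict upper coverage bound
  support <- matrix(rep(rowSums(pass1), m), n, m)
  readmit <- !pass1 & called & qual_ok & dp_ok & band_low_ok &
    !band_high_ok & relaxed_high_ok & balance_ok & pl_ok & ad_dp_ok &
    support >= cfg$relax_support
  pass <- pass1 | readmit
  first_fail <- matrix(NA_character_, n, m)
  set_fail <- function(ff, cond, rule) {
    sel <- !pass & is.na(ff) & cond
    ff[sel] <- rule
    ff
  }
  first_fail <- set_fail(first_fail, !called, "missing")
  first_fail <- set_fail(first_fail, !qual_ok, "qual")
  first_fail <- set_fail(first_fail, !dp_ok, "dp_min")
  first_fail <- set_fail(first_fail, !(band_low_ok & band_high_ok), "coverage")
  first_fail <- set_fail(first_fail, !balance_ok, "allele_balance")
  first_fail <- set_fail(first_fail, !pl_ok, "hom_pl")
  first_fail <- set_fail(first_fail, !ad_dp_ok, "ad_dp")
  counts <- table(factor(first_fail[!pass],
                         levels = c("missing", "qual", "dp_min", "coverage",
                                    "allele_balance", "hom_pl", "ad_dp")))
  structure(
    list(pass = pass, pass1 = pass1, first_fail = first_fail, modal = modal,
         n_readmitted = sum(readmit),
         rule_counts = tibble::tibble(rule = names(counts),
                                      n_failed = as.integer(counts)),
         cfg = cfg),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s/%s calls pass (%.1f%%); %d re-admitted by coverage relaxation\n",
              format(sum(x$pass), big.mark = ","),
              format(length(x$pass), big.mark = ","),
              100 * mean(x$pass), x$n_readmitted))
  print(x$rule_counts)
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    site = rep(seq_len(nrow(x$pass)), times = ncol(x$pass)),
    sample = rep(colnames(x$pass) %||% as.character(seq_len(ncol(x$pass))),
                 each = nrow(x$pass)),
    pass = as.vector(x$pass),
    first_fail = as.vector(x$first_fail))
}

#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(n_calls = length(x$pass), n_pass = sum(x$pass),
                 pass_rate = mean(x$pass), n_readmitted = x$n_readmitted)
}

#' Site-level retention
#'
#' A site is retained iff it is outside repetitive DNA, more than the
#' configured fraction of samples pass the call filters (strict inequality),
#' and at least `min_carriers` passing samples carry the alternate allele.
#'
#' @param report A `filter_report` from [apply_call_filters()].
#' @param ds The same [genotype_dataset()].
#' @param cfg A [filter_config()].
#' @return Tibble with per-site `n_pass`, `frac_pass`, `n_carriers`,
#'   `masked`, `retained`.
#' @export
select_sites <- function(report, ds, cfg = report$cfg) {
  n_pass <- rowSums(report$pass)
  frac <- n_pass / n_samples(ds)
  carrier <- report$pass & !is.na(ds$gt) & ds$gt > 0L
  n_carriers <- rowSums(carrier)
  tibble::tibble(
    chrom = ds$sites$chrom, pos = ds$sites$pos,
    n_pass = n_pass, frac_pass = frac, n_carriers = n_carriers,
    masked = ds$sites$masked,
    retained = !ds$sites$masked & frac > cfg$site_retention &
      n_carriers >= cfg$min_carriers)
}

#' Run the whole filter cascade
#'
#' Applies [apply_call_filters()] and [select_sites()], sets failing calls to
#' missing, and drops non-retained sites.
#'
#' @param ds A [genotype_dataset()] with metadata.
#' @param cfg A [filter_config()].
#' @return List with `dataset` (filtered), `report`, `sites` (the
#'   [select_sites()] table).
#' @export
filter_cohort <- function(ds, cfg = filter_config()) {
  report <- apply_call_filters(ds, cfg)
  site_tab <- select_sites(report, ds, cfg)
  out <- ds
  drop <- !report$pass
  out$gt[drop] <- NA_integer_
  if (!is.null(out$hap1)) {
    out$hap1[drop] <- NA_integer_
    out$hap2[drop] <- NA_integer_
  }
  out <- subset_sites(out, site_tab$retained)
  attr(out, "mask") <- attr(ds, "mask")
  attr(out, "sim_config") <- attr(ds, "sim_config")
  attr(out, "modal_coverage") <- report$modal
  list(dataset = out, report = report, sites = site_tab)
}
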