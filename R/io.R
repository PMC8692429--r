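#' Load a genotype cohort from VCF, repeat mask and group table
#'
#' Reads a VCF (GT required; DP/AD/PL/QUAL used when present), flags sites
#' inside a BED repeat mask (they are kept, not removed), and attaches sample
#' group labels from a two-column TSV (`sample<TAB>group`). Multiallelic and
#' indel records are skipped with a logged count; every VCF sample must be
#' present in the group table.
#'
#' @param vcf_path Path to a VCF 4.x file (plain text).
#' @param mask_path Optional path to a BED3 repeat mask.
#' @param groups_path Path to the sample-group TSV.
#' @return A [genotype_dataset()]; the number of skipped records is stored in
#'   attribute `n_skipped`.
#' @export
load_cohort <- function(vcf_path, mask_path = NULL, groups_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  groups <- read_group_table(groups_path)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(vcf_samples, groups$sample)
  if (length(missing)) {
    stop("sample(s) in VCF missing from groups file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  snp <- !is.na(fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped) {
    message("skipped ", n_skipped, " multiallelic/indel record(s)")
  }
  keep <- which(snp)
  sites <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    masked = FALSE
  )
  gt_str <- v@gt[keep, -1, drop = FALSE]
  fmt <- strsplit(v@gt[keep, 1], ":", fixed = TRUE)
  parts <- strsplit(as.vector(gt_str), ":", fixed = TRUE)
  nf <- lengths(parts)
  get_field <- function(name) {
    idx <- vapply(fmt, function(f) match(name, f), integer(1))
    if (all(is.na(idx))) return(NULL)
    pick <- rep(idx, times = ncol(gt_str))
    flat <- unlist(parts, use.names = FALSE)
    offset <- cumsum(c(0, nf[-length(nf)]))
    val <- rep(NA_character_, length(parts))
    ok <- !is.na(pick) & pick <= nf
    val[ok] <- flat[offset[ok] + pick[ok]]
    matrix(val, nrow(gt_str), ncol(gt_str))
  }
  gtf <- get_field("GT")
  if (is.null(gtf)) stop("VCF has no GT field at ", vcf_path, call. = FALSE)
  bad <- !is.na(gtf) & !gtf %in% c(
    "0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1", "./.", ".", ".|.")
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype '%s' at %s:%s", gtf[bad][1],
                 sites$chrom[i[1]], sites$pos[i[1]]), call. = FALSE)
  }
  dose <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  gt <- matrix(dose(as.vector(gtf)), nrow(gtf), ncol(gtf))
  phased <- !is.na(gtf) & grepl("|", gtf, fixed = TRUE) & gtf != ".|."
  hap1 <- hap2 <- NULL
  if (any(phased)) {
    hap1 <- matrix(NA_integer_, nrow(gtf), ncol(gtf))
    hap2 <- hap1
    hap1[phased] <- as.integer(substr(gtf[phased], 1, 1))
    hap2[phased] <- as.integer(substr(gtf[phased], 3, 3))
  }
  int_mat <- function(m) {
    if (is.null(m)) return(NULL)
    out <- suppressWarnings(matrix(as.integer(as.vector(m)), nrow(m), ncol(m)))
    out
  }
  dp <- int_mat(get_field("DP"))
  adf <- get_field("AD")
  ad_ref <- ad_alt <- NULL
  if (!is.null(adf)) {
    sp <- strsplit(as.vector(adf), ",", fixed = TRUE)
    ad_ref <- matrix(suppressWarnings(as.integer(vapply(sp, `[`, "", 1))),
                     nrow(adf), ncol(adf))
    ad_alt <- matrix(suppressWarnings(as.integer(vapply(sp, function(x)
      if (length(x) >= 2) x[2] else NA_character_, ""))), nrow(adf), ncol(adf))
  }
  plf <- get_field("PL")
  pl <- NULL
  if (!is.null(plf)) {
    sp <- strsplit(as.vector(plf), ",", fixed = TRUE)
    pl <- array(NA_integer_, c(nrow(plf), ncol(plf), 3))
    for (k in 1:3) {
      pl[, , k] <- matrix(suppressWarnings(as.integer(vapply(sp, function(x)
        if (length(x) >= k) x[k] else NA_character_, ""))), nrow(plf), ncol(plf))
    }
  }
  samples <- tibble::tibble(
    sample = vcf_samples,
    group = groups$group[match(vcf_samples, groups$sample)])
  chrom_lengths <- parse_contig_lengths(v@meta)
  ds <- genotype_dataset(sites, samples, gt, dp = dp, ad_ref = ad_ref,
                         ad_alt = ad_alt, pl = pl, hap1 = hap1, hap2 = hap2,
                         chrom_lengths = chrom_lengths)
  if (!is.null(mask_path)) {
    mask <- read_repeat_mask(mask_path)
    ds$sites$masked <- sites_in_mask(mask, ds$sites$chrom, ds$sites$pos)
    attr(ds, "mask") <- mask
  }
  attr(ds, "n_skipped") <- n_skipped
  ds
}

parse_contig_lengths <- function(meta) {
  contig <- grep("^##contig=", meta, value = TRUE)
  if (!length(contig)) return(NULL)
  id <- stringr::str_match(contig, "ID=([^,>]+)")[, 2]
  len <- as.numeric(stringr::str_match(contig, "length=([0-9]+)")[, 2])
  stats::setNames(len, id)
}

#' @rdname load_cohort
#' @param path Path to a `sample<TAB>group` TSV (no header).
#' @export
read_group_table <- function(path) {
  readr::read_tsv(path, col_names = c("sample", "group"), col_types = "cc",
                  progress = FALSE)
}

#' @rdname load_cohort
#' @param groups Tibble with columns `sample`, `group`.
#' @export
write_group_table <- function(groups, path) {
  readr::write_tsv(groups[, c("sample", "group")], path, col_names = FALSE)
  invisible(path)
}

#' Write a cohort as VCF
#'
#' Serializes a [genotype_dataset()] as a plain-text VCF 4.2 file with
#' `GT[:DP:AD:PL]` per call. Calls whose stored phase is consistent with the
#' genotype are written phased (`|`); all others unphased (`/`). The output
#' is deterministic: the same dataset always yields byte-identical files.
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @export
write_vcf <- function(ds, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(ds$chrom_lengths),
            as.integer(ds$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  with_meta <- has_metadata(ds)
  if (with_meta) {
    meta <- c(meta,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">")
  }
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", ds$samples$sample), collapse = "\t")
  n <- n_sites(ds); m <- n_samples(ds)
  gt_sym <- matrix("./.", n, m)
  called <- !is.na(ds$gt)
  unph <- c("0/0", "0/1", "1/1")
  gt_sym[called] <- unph[ds$gt[called] + 1L]
  if (has_phase(ds)) {
    ok <- called & !is.na(ds$hap1) & !is.na(ds$hap2) &
      (ds$hap1 + ds$hap2 == ds$gt)
    gt_sym[ok] <- paste0(ds$hap1[ok], "|", ds$hap2[ok])
  }
  if (with_meta) {
    cell <- matrix(paste0(gt_sym, ":", ifelse(is.na(ds$dp), ".", ds$dp), ":",
                          ifelse(is.na(ds$ad_ref), ".", ds$ad_ref), ",",
                          ifelse(is.na(ds$ad_alt), ".", ds$ad_alt), ":",
                          ifelse(is.na(ds$pl[, , 1]), ".", ds$pl[, , 1]), ",",
                          ifelse(is.na(ds$pl[, , 2]), ".", ds$pl[, , 2]), ",",
                          ifelse(is.na(ds$pl[, , 3]), ".", ds$pl[, , 3])),
                   n, m)
    cell[!called] <- "./.:.:.,.:.,.,."
    fmt <- "GT:DP:AD:PL"
  } else {
    cell <- gt_sym
    fmt <- "GT"
  }
  body <- paste(ds$sites$chrom, ds$sites$pos, ".", ds$sites$ref, ds$sites$alt,
                ifelse(is.na(ds$sites$qual), ".",
                       formatC(ds$sites$qual, format = "g", digits = 8)),
                "PASS", ".", fmt, sep = "\t")
  sample_cols <- apply(cell, 1, paste, collapse = "\t")
  writeLines(c(meta, header, paste(body, sample_cols, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Write a simulated cohort and its companion files
#'
#' Writes the VCF, the repeat mask BED, and the sample-group TSV for a
#' dataset, so a round trip through [load_cohort()] reproduces it.
#'
#' @param ds A [genotype_dataset()] (with `attr(ds, "mask")` if masked).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named list of the written paths.
#' @export
write_cohort <- function(ds, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    mask = file.path(dir, paste0(prefix, ".mask.bed")),
    groups = file.path(dir, paste0(prefix, ".groups.tsv")))
  write_vcf(ds, paths$vcf)
  mask <- attr(ds, "mask")
  if (is.null(mask)) mask <- repeat_mask()
  write_repeat_mask(mask, paths$mask)
  write_group_table(ds$samples, paths$groups)
  paths
}
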