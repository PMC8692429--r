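#' Allele-specific expression test with Stouffer combination
#'
#' For each gene (and sample), every replicate's allele-resolved read counts
#' are tested against the null reference-allele fraction with a two-sided
#' exact binomial test; the p-value is converted to a signed z score (sign =
#' direction of the imbalance) and the replicates are combined with a
#' weighted Stouffer meta-analysis, `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`,
#' with default weights `w_i = sqrt(ref_i + alt_i)`. The allelic imbalance
#' ratio `r` is the mean over replicates of `ref / (ref + alt)`. Replicates
#' with zero total are dropped (and counted); genes with no usable replicate
#' are returned with `NA` statistics and flagged.
#'
#' @param counts Tibble with columns `gene`, `replicate`, `ref_count`,
#'   `alt_count`, and optionally `sample` and `fpkm`.
#' @param weights `"sqrt_depth"` (default), `"equal"`, or a function of the
#'   replicate depth vector returning weights.
#' @param null_ratio Null reference-allele fraction.
#' @param alpha Significance threshold on the combined two-sided p.
#' @param adjust Multiple-testing adjustment across genes passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return Tibble of class `ase_result`, one row per gene (x sample):
#'   `n_rep`, `n_dropped`, `r`, `z` (Stouffer Z), `p`, `significant`,
#'   `undefined`, plus `fpkm`, `fpkm_ref`, `fpkm_alt` when FPKM is supplied.
#' @export
ase_test <- function(counts, weights = "sqrt_depth", null_ratio = 0.5,
                     alpha = 0.05, adjust = "none") {
  counts <- tibble::as_tibble(counts)
  if (!"sample" %in% names(counts)) counts$sample <- "S1"
  if (!"fpkm" %in% names(counts)) counts$fpkm <- NA_real_
  stopifnot(all(counts$ref_count >= 0), all(counts$alt_count >= 0))
  wfun <- if (is.function(weights)) weights else switch(
    weights,
    sqrt_depth = function(n) sqrt(n),
    equal = function(n) rep(1, length(n)),
    stop("unknown weights: ", weights, call. = FALSE))
  one <- function(d, key) {
    tot <- d$ref_count + d$alt_count
    keep <- tot > 0
    n_drop <- sum(!keep)
    d <- d[keep, ]; tot <- tot[keep]
    if (nrow(d) == 0) {
      return(tibble::tibble(n_rep = 0L, n_dropped = n_drop, r = NA_real_,
                            z = NA_real_, p = NA_real_, undefined = TRUE,
                            fpkm = first_or_na(d$fpkm)))
    }
    pvals <- vapply(seq_len(nrow(d)), function(i) {
      stats::binom.test(d$ref_count[i], tot[i], p = null_ratio)$p.value
    }, numeric(1))
    pvals <- pmax(pmin(pvals, 1), .Machine$double.xmin)
    direction <- sign(d$ref_count / tot - null_ratio)
    z_i <- direction * stats::qnorm(1 - pvals / 2)
    w <- wfun(tot)
    Z <- sum(w * z_i) / sqrt(sum(w^2))
    tibble::tibble(n_rep = nrow(d), n_dropped = n_drop,
                   r = mean(d$ref_count / tot),
                   z = Z, p = 2 * stats::pnorm(-abs(Z)), undefined = FALSE,
                   fpkm = first_or_na(d$fpkm))
  }
  out <- dplyr::reframe(dplyr::group_by(counts, .data$gene, .data$sample),
                        one(dplyr::pick(dplyr::everything()), NULL))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  if (all(is.na(out$fpkm))) {
    out$fpkm <- NULL
  } else {
    out <- apportion_expression(out)
  }
  class(out) <- c("ase_result", class(out))
  out
}

first_or_na <- function(x) if (is.null(x) || !length(x)) NA_real_ else x[1]

#' Apportion gene expression between alleles
#'
#' Splits each gene's cumulative FPKM proportionally to the allelic imbalance
#' ratio: `fpkm_ref = fpkm * r`, `fpkm_alt = fpkm * (1 - r)`; the two always
#' sum to the total. Undefined ratios give undefined allele expression.
#'
#' @param result An [ase_test()] result (or any tibble with `r`).
#' @param fpkm Total FPKM per row; defaults to the `fpkm` column.
#' @return The input with `fpkm_ref` and `fpkm_alt` columns.
#' @export
apportion_expression <- function(result, fpkm = NULL) {
  if (is.null(fpkm)) {
    fpkm <- if ("fpkm" %in% names(result)) result$fpkm else NULL
  }
  if (is.null(fpkm)) stop("no FPKM values supplied", call. = FALSE)
  stopifnot(all(fpkm >= 0, na.rm = TRUE))
  result$fpkm <- fpkm
  result$fpkm_ref <- fpkm * result$r
  result$fpkm_alt <- fpkm * (1 - result$r)
  result
}

#' @export
glance.ase_result <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 rejection_rate = mean(x$significant[!x$undefined]),
                 n_undefined = sum(x$undefined))
}
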