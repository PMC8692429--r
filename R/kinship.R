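#' IBD window-state thresholds
#'
#' Thresholds of the per-window IBD state caller. A window is called IBD = 0
#' when the opposite-homozygote fraction exceeds `t0`; otherwise IBD = 2 when
#' the identical-genotype fraction exceeds `t2` and the genotypic distance is
#' below `d2`; otherwise IBD = 1. Windows with fewer than `min_sites`
#' informative sites are left unclassified.
#'
#' @param t0 Opposite-homozygote fraction above which a window is IBD = 0.
#' @param t2 Identical-genotype fraction above which a window may be IBD = 2.
#' @param d2 Genotypic distance below which a window may be IBD = 2.
#' @param t1 Identity-by-state ratio for the explicit IBD = 1 call (kept for
#'   completeness; windows failing it are still assigned the residual state 1).
#' @param min_sites Minimum informative sites per window.
#' @return A list of class `ibd_thresholds`.
#' @export
ibd_thresholds <- function(t0 = 0.02, t2 = 0.95, d2 = 0.03, t1 = 0.98,
                           min_sites = 10) {
  structure(list(t0 = t0, t2 = t2, d2 = d2, t1 = t1, min_sites = min_sites),
            class = "ibd_thresholds")
}

#' Windowed IBD profile of a sample pair
#'
#' For each window the profile records the number of informative sites (both
#' samples called), the identity-by-state ratio (fraction of sites sharing at
#' least one allele), the genotypic distance (mean absolute dosage difference
#' divided by 2), the opposite-homozygote and identical-genotype fractions,
#' and the called IBD state. Maximal runs of equal state are merged into
#' segments whose length is the physical span (Mb) of their constituent
#' windows, and genome summaries are computed: percent of classified length
#' in IBD 0/1/2, standard deviations of IBD = 0 and IBD = 2 segment lengths
#' genome-wide, and the standard deviation across chromosomes of the mean
#' IBD = 2 segment length.
#'
#' @param ds A [genotype_dataset()].
#' @param pair Character vector of two sample ids.
#' @param ws A nonrep-fixed [window_set][make_windows()].
#' @param thresholds An [ibd_thresholds()].
#' @param assignment Optional precomputed [assign_sites()] table.
#' @param include_partial Include partial trailing windows (default `FALSE`).
#' @return An object of class `ibd_profile`: list with `pair`, `windows`
#'   (tibble), `segments` (tibble), `summary` (list) and `low_confidence`
#'   (more than half of the windows unclassified).
#' @export
ibd_profile <- function(ds, pair, ws, thresholds = ibd_thresholds(),
                        assignment = NULL, include_partial = FALSE) {
  stopifnot(length(pair) == 2)
  cols <- match(pair, ds$samples$sample)
  if (anyNA(cols)) {
    stop("sample(s) not in dataset: ",
         paste(pair[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  if (is.null(assignment)) assignment <- assign_sites(ds, ws)
  wtab <- if (include_partial) ws else ws[!ws$partial, ]
  d1 <- ds$gt[, cols[1]]; d2 <- ds$gt[, cols[2]]
  s <- assignment$site; w <- assignment$window
  ok <- !is.na(d1[s]) & !is.na(d2[s]) & w %in% wtab$index
  s <- s[ok]; w <- w[ok]
  dif <- abs(d1[s] - d2[s])
  grp <- factor(w, levels = wtab$index)
  agg <- function(x) {
    out <- rep(0, nrow(wtab))
    r <- rowsum(x, grp)
    out[match(rownames(r), as.character(wtab$index))] <- r[, 1]
    out
  }
  n_inf <- agg(rep(1, length(w)))
  opp <- agg(as.numeric(dif == 2))
  ident <- agg(as.numeric(dif == 0))
  gd_sum <- agg(dif / 2)
  win <- dplyr::mutate(
    wtab,
    n_informative = n_inf,
    opposite_hom_fraction = ifelse(n_inf > 0, opp / n_inf, NA_real_),
    identical_genotype_fraction = ifelse(n_inf > 0, ident / n_inf, NA_real_),
    ibs_ratio = ifelse(n_inf > 0, 1 - opp / n_inf, NA_real_),
    genotypic_distance = ifelse(n_inf > 0, gd_sum / n_inf, NA_real_))
  th <- thresholds
  state <- rep(NA_integer_, nrow(win))
  classif <- win$n_informative >= th$min_sites
  state[classif] <- 1L
  state[classif & win$opposite_hom_fraction > th$t0] <- 0L
  is2 <- classif & !(win$opposite_hom_fraction > th$t0) &
    win$identical_genotype_fraction > th$t2 & win$genotypic_distance < th$d2
  state[is2] <- 2L
  win$state <- state
  segments <- ibd_segments(win)
  summary <- ibd_summaries(segments)
  structure(
    list(pair = pair, windows = win, segments = segments, summary = summary,
         thresholds = th,
         low_confidence = mean(is.na(state)) > 0.5),
    class = "ibd_profile")
}

# maximal runs of equal state over classified windows, per chromosome;
# segment length = physical span of constituent windows (Mb)
ibd_segments <- function(win) {
  cl <- win[!is.na(win$state), ]
  if (nrow(cl) == 0) {
    return(tibble::tibble(chrom = character(), state = integer(),
                          start = double(), end = double(),
                          n_windows = integer(), length_mb = double()))
  }
  cl <- dplyr::arrange(cl, .data$chrom, .data$start)
  new_run <- c(TRUE, cl$chrom[-1] != cl$chrom[-nrow(cl)] |
                 cl$state[-1] != cl$state[-nrow(cl)])
  run <- cumsum(new_run)
  dplyr::summarise(
    dplyr::group_by(cl, run = run),
    chrom = .data$chrom[1], state = .data$state[1],
    start = min(.data$start), end = max(.data$end),
    n_windows = dplyr::n(),
    length_mb = sum(.data$end - .data$start) / 1e6,
    .groups = "drop")[, -1]
}

ibd_summaries <- function(segments) {
  len_by_state <- function(s) sum(segments$length_mb[segments$state == s])
  L0 <- len_by_state(0L); L1 <- len_by_state(1L); L2 <- len_by_state(2L)
  total <- L0 + L1 + L2
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  seg0 <- segments$length_mb[segments$state == 0L]
  seg2 <- segments$length_mb[segments$state == 2L]
  chr_means <- tapply(seg2, segments$chrom[segments$state == 2L], mean)
  list(
    L0 = L0, L1 = L1, L2 = L2, classified_mb = total,
    pct0 = if (total > 0) 100 * L0 / total else NA_real_,
    pct1 = if (total > 0) 100 * L1 / total else NA_real_,
    pct2 = if (total > 0) 100 * L2 / total else NA_real_,
    sd0_genome = sd0(seg0),
    sd2_genome = sd0(seg2),
    sd2_chr = sd0(as.numeric(chr_means)))
}

#' @export
print.ibd_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ibd_profile> %s - %s%s\n", x$pair[1], x$pair[2],
              if (x$low_confidence) " (low confidence)" else ""))
  cat(sprintf("  IBD0 %.1f%% | IBD1 %.1f%% | IBD2 %.1f%% of %.1f classified Mb\n",
              s$pct0, s$pct1, s$pct2, s$classified_mb))
  cat(sprintf("  sd0 %.3f Mb, sd2 %.3f Mb, sd2 across chromosomes %.3f Mb\n",
              s$sd0_genome, s$sd2_genome, s$sd2_chr))
  invisible(x)
}

#' @export
tidy.ibd_profile <- function(x, ...) x$windows

#' @export
glance.ibd_profile <- function(x, ...) {
  s <- x$summary
  tibble::tibble(sample1 = x$pair[1], sample2 = x$pair[2],
                 pct0 = s$pct0, pct1 = s$pct1, pct2 = s$pct2,
                 classified_mb = s$classified_mb,
                 sd0_genome = s$sd0_genome, sd2_genome = s$sd2_genome,
                 sd2_chr = s$sd2_chr,
                 hap_distance = haplotypic_distance(x),
                 low_confidence = x$low_confidence)
}

#' Haplotypic distance of a profile
#'
#' Fraction of haplotype length not shared: `(L0 + L1/2) / (L0 + L1 + L2)`.
#' A clone profile gives 0, a parent-offspring-style profile (all IBD = 1)
#' gives 0.5, and fully disjoint genomes give 1. `NA` (with a warning) when
#' no window could be classified.
#'
#' @param profile An [ibd_profile()].
#' @return A number in [0, 1], or `NA`.
#' @export
haplotypic_distance <- function(profile) {
  s <- profile$summary
  if (s$classified_mb == 0) {
    warning("no classified windows; haplotypic distance undefined")
    return(NA_real_)
  }
  (s$L0 + s$L1 / 2) / s$classified_mb
}

#' Relationship-classification thresholds
#'
#' The reference decision-list thresholds, evaluated in order clone, PO
#' (parent-offspring), FS (full sibs), HS (half sibs), and `gt2nd`
#' (more distant than second degree) otherwise. Percentages are of classified
#' physical genome length; dispersion statistics are in Mb.
#' `clone_ibd1_min = 0` disables the clone rule's IBD = 1 lower bound (the
#' reference 3% bound excludes perfectly identical pairs).
#'
#' @param clone_ibd1_min Clone rule's minimum IBD = 1 percentage.
#' @return A list of class `relationship_rules`.
#' @export
relationship_rules <- function(clone_ibd1_min = 3) {
  structure(list(clone_ibd1_min = clone_ibd1_min), class = "relationship_rules")
}

#' Classify the relationship of a sample pair
#'
#' Decision list over the profile summaries, first match wins:
#' clone (IBD0 < 3%, IBD1 > 3%, IBD2 > 90%); PO (IBD0 < 15%, IBD1 > 50%,
#' sd of IBD0 segment length < 0.1 Mb); FS (10% < IBD0 < 20%, IBD1 < 60%,
#' 0.1 < sd IBD0 < 0.2 Mb, sd IBD2 > 0.23 Mb, sd across chromosomes of mean
#' IBD2 segment length > 3 Mb); HS (12% < IBD0 < 50%, IBD1 > 60%,
#' sd IBD2 < 0.23 Mb, sd2 across chromosomes < 5 Mb); otherwise `gt2nd`.
#'
#' @param profile An [ibd_profile()] (or a list with a compatible `summary`).
#' @param rules A [relationship_rules()].
#' @return A `relationship_call`: list with `category` and a `trace` tibble
#'   listing every threshold comparison.
#' @export
classify_relationship <- function(profile, rules = relationship_rules()) {
  s <- profile$summary
  need <- c("pct0", "pct1", "pct2", "sd0_genome", "sd2_genome", "sd2_chr")
  miss <- need[!vapply(need, function(k) !is.null(s[[k]]) && !is.na(s[[k]]),
                       logical(1))]
  if (length(miss)) {
    stop("missing summary statistic(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trace <- list()
  chk <- function(rule, stat, op, thr) {
    v <- s[[stat]]
    ok <- switch(op, `<` = v < thr, `>` = v > thr)
    trace[[length(trace) + 1]] <<- tibble::tibble(
      rule = rule, statistic = stat, comparison = op, threshold = thr,
      value = v, passed = ok)
    ok
  }
  category <-
    if (chk("clone", "pct0", "<", 3) &
        (rules$clone_ibd1_min == 0 | chk("clone", "pct1", ">", rules$clone_ibd1_min)) &
        chk("clone", "pct2", ">", 90)) "clone"
    else if (chk("PO", "pct0", "<", 15) & chk("PO", "pct1", ">", 50) &
             chk("PO", "sd0_genome", "<", 0.1)) "PO"
    else if (chk("FS", "pct0", ">", 10) & chk("FS", "pct0", "<", 20) &
             chk("FS", "pct1", "<", 60) &
             chk("FS", "sd0_genome", ">", 0.1) & chk("FS", "sd0_genome", "<", 0.2) &
             chk("FS", "sd2_genome", ">", 0.23) & chk("FS", "sd2_chr", ">", 3)) "FS"
    else if (chk("HS", "pct0", ">", 12) & chk("HS", "pct0", "<", 50) &
             chk("HS", "pct1", ">", 60) &
             chk("HS", "sd2_genome", "<", 0.23) & chk("HS", "sd2_chr", "<", 5)) "HS"
    else "gt2nd"
  structure(list(category = category, trace = dplyr::bind_rows(trace)),
            class = "relationship_call")
}

#' @export
print.relationship_call <- function(x, ...) {
  cat("<relationship_call>", x$category, "\n")
  print(x$trace)
  invisible(x)
}

#' Pairwise relationship network of a cohort
#'
#' Profiles and classifies every unordered sample pair and returns the table
#' of detected relationships (category other than `gt2nd`), with the profile
#' summaries and haplotypic distance per edge.
#'
#' @param ds A [genotype_dataset()].
#' @param ws A nonrep-fixed [window_set][make_windows()].
#' @param thresholds An [ibd_thresholds()].
#' @param rules A [relationship_rules()].
#' @param pairs Optional 2-column matrix/tibble of sample-id pairs to restrict
#'   to.
#' @param keep_all Also return `gt2nd` pairs (default `FALSE`).
#' @return Tibble with one row per (retained) pair: ids, `category`,
#'   summaries, `hap_distance`, `low_confidence`.
#' @export
relationship_network <- function(ds, ws, thresholds = ibd_thresholds(),
                                 rules = relationship_rules(), pairs = NULL,
                                 keep_all = FALSE) {
  if (n_samples(ds) < 2) stop("need at least two samples", call. = FALSE)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ds$samples$sample, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  assignment <- assign_sites(ds, ws)
  rows <- purrr::map(seq_len(nrow(pairs)), function(k) {
    prof <- ibd_profile(ds, pairs[k, ], ws, thresholds, assignment = assignment)
    call <- classify_relationship(prof, rules)
    out <- suppressWarnings(glance(prof))
    out$category <- call$category
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "category", .after = "sample2")
  if (!keep_all) out <- out[out$category != "gt2nd", ]
  out
}
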