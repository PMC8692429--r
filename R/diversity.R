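#' Windowed nucleotide diversity
#'
#' Per window, `pi` is the sum over sites of the unbiased per-site
#' heterozygosity `[n/(n-1)] * 2 p (1-p)` (with `n` the called haplotypes at
#' the site, so missing calls reduce `n` site-wise), divided by the window's
#' non-repetitive length. This equals the average pairwise difference per
#' non-repetitive bp.
#'
#' @param ds A [genotype_dataset()].
#' @param group Group label(s) defining the sample set.
#' @param ws A [window_set][make_windows()].
#' @param include_partial Include partial windows (default `FALSE`).
#' @return Tibble: window columns plus `n_sites` and `pi`. Windows with zero
#'   non-repetitive bp are skipped.
#' @export
nucleotide_diversity_scan <- function(ds, group, ws, include_partial = FALSE) {
  cols <- which(ds$samples$group %in% group)
  if (length(cols) < 1) stop("no samples in group", call. = FALSE)
  sub <- ds$gt[, cols, drop = FALSE]
  n_hap <- 2 * rowSums(!is.na(sub))
  p <- rowSums(sub, na.rm = TRUE) / n_hap
  term <- ifelse(n_hap >= 2, n_hap / (n_hap - 1) * 2 * p * (1 - p), 0)
  wtab <- if (include_partial) ws else ws[!ws$partial, ]
  wtab <- wtab[wtab$nonrep_bp > 0, ]
  asg <- assign_sites(ds, ws)
  asg <- asg[asg$window %in% wtab$index, ]
  grp <- factor(asg$window, levels = wtab$index)
  wsum <- function(x) {
    out <- rep(0, nrow(wtab))
    r <- rowsum(x[asg$site], grp)
    out[match(rownames(r), as.character(wtab$index))] <- r[, 1]
    out
  }
  dplyr::mutate(tibble::as_tibble(wtab),
                n_sites = wsum(rep(1, length(term))),
                pi = wsum(term) / .data$nonrep_bp)
}

#' Blockwise haplotype diversity with spline smoothing
#'
#' Haplotype (gene) diversity is computed in blocks of `block_size`
#' consecutive variant sites within each chromosome:
#' `H = [n/(n-1)] * (1 - sum p_k^2)` over the distinct block haplotypes,
#' where `n` is the number of haplotypes fully called in the block. The
#' plotted series is the mean of `n_avg` consecutive (non-overlapping)
#' blocks, and a cubic smoothing spline (penalty chosen by generalized
#' cross-validation unless `spar` is given) is fitted through the plotted
#' points per chromosome.
#'
#' @param ds A phased [genotype_dataset()].
#' @param group Group label(s).
#' @param block_size Variant sites per block.
#' @param n_avg Blocks averaged per plotted point.
#' @param spar Optional `smooth.spline` smoothing parameter.
#' @return A `diversity_track`: list with `blocks` (tibble: `chrom`, `pos`
#'   midpoint, `H`, `n_hap`) and `points` (tibble: `chrom`, `pos`, `H`,
#'   `smooth`). Chromosomes with fewer than `block_size` sites contribute no
#'   blocks (their count is in attribute `n_skipped_chrom`).
#' @export
haplotype_diversity_scan <- function(ds, group, block_size = 5, n_avg = 50,
                                     spar = NULL) {
  if (!has_phase(ds)) {
    stop("haplotype diversity needs phased calls (hap1/hap2)", call. = FALSE)
  }
  cols <- which(ds$samples$group %in% group)
  H <- cbind(ds$hap1[, cols, drop = FALSE], ds$hap2[, cols, drop = FALSE])
  blocks <- list()
  skipped <- 0L
  for (ch in unique(ds$sites$chrom)) {
    sel <- which(ds$sites$chrom == ch)
    nb <- floor(length(sel) / block_size)
    if (nb == 0) {
      skipped <- skipped + 1L
      next
    }
    bi <- rep(seq_len(nb), each = block_size)
    use <- sel[seq_len(nb * block_size)]
    hv <- vapply(seq_len(nb), function(b) {
      rows <- use[bi == b]
      block_hap_diversity(H[rows, , drop = FALSE])
    }, numeric(2))
    blocks[[ch]] <- tibble::tibble(
      chrom = ch,
      block = seq_len(nb),
      pos = vapply(seq_len(nb), function(b) mean(ds$sites$pos[use[bi == b]]),
                   numeric(1)),
      H = hv[1, ], n_hap = as.integer(hv[2, ]))
  }
  blocks <- dplyr::bind_rows(blocks)
  if (nrow(blocks) == 0) {
    blocks <- tibble::tibble(chrom = character(), block = integer(),
                             pos = double(), H = double(), n_hap = integer())
  }
  points <- dplyr::bind_rows(lapply(split(blocks, blocks$chrom), function(b) {
    ng <- floor(nrow(b) / n_avg)
    if (ng == 0) return(NULL)
    gi <- rep(seq_len(ng), each = n_avg)
    use <- seq_len(ng * n_avg)
    tibble::tibble(
      chrom = b$chrom[1],
      pos = as.vector(tapply(b$pos[use], gi, mean)),
      H = as.vector(tapply(b$H[use], gi, mean)))
  }))
  if (nrow(points)) {
    points <- dplyr::bind_rows(lapply(split(points, points$chrom), function(p) {
      if (nrow(p) >= 4) {
        fit <- if (is.null(spar)) stats::smooth.spline(p$pos, p$H) else
          stats::smooth.spline(p$pos, p$H, spar = spar)
        p$smooth <- stats::predict(fit, p$pos)$y
      } else {
        p$smooth <- p$H
      }
      p
    }))
  }
  structure(list(blocks = blocks, points = points,
                 block_size = block_size, n_avg = n_avg),
            class = "diversity_track")
}

# unbiased gene diversity of one site-block; haplotypes with missing alleles
# in the block are dropped
block_hap_diversity <- function(mat) {
  complete <- colSums(is.na(mat)) == 0
  n <- sum(complete)
  if (n < 2) return(c(NA_real_, n))
  key <- apply(mat[, complete, drop = FALSE], 2, paste, collapse = "")
  pk <- table(key) / n
  c(n / (n - 1) * (1 - sum(pk^2)), n)
}

#' @export
print.diversity_track <- function(x, ...) {
  cat(sprintf("<diversity_track> %d blocks of %d sites; %d plotted points (means of %d blocks)\n",
              nrow(x$blocks), x$block_size, nrow(x$points), x$n_avg))
  invisible(x)
}

#' @export
tidy.diversity_track <- function(x, ...) x$points

#' Detect sweep-like diversity valleys
#'
#' Flags contiguous runs of plotted points whose smoothed haplotype diversity
#' falls below the genome-wide `quantile` of smoothed values, merging runs
#' separated by at most `merge_gap` points; each call reports the nadir
#' (position of the minimum smoothed value).
#'
#' @param track A [haplotype_diversity_scan()] result.
#' @param quantile Genome-wide quantile defining the threshold.
#' @param merge_gap Maximum gap (points) across which runs are merged.
#' @return Tibble: `chrom`, `start`, `end` (positions of the first and last
#'   point in the run), `nadir`, `min_smooth`, `n_points`.
#' @export
detect_sweeps <- function(track, quantile = 0.05, merge_gap = 2) {
  pts <- track$points
  if (nrow(pts) == 0) return(empty_sweep_table())
  thr <- stats::quantile(pts$smooth, quantile, names = FALSE)
  out <- lapply(split(pts, pts$chrom), function(p) {
    below <- which(p$smooth < thr)
    if (!length(below)) return(NULL)
    grp <- cumsum(c(1, diff(below) > merge_gap + 1))
    dplyr::bind_rows(lapply(split(below, grp), function(run) {
      run <- seq(min(run), max(run))  # fill merged gaps
      tibble::tibble(
        chrom = p$chrom[1],
        start = p$pos[run[1]], end = p$pos[run[length(run)]],
        nadir = p$pos[run[which.min(p$smooth[run])]],
        min_smooth = min(p$smooth[run]),
        n_points = length(run))
    }))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty_sweep_table() else out
}

empty_sweep_table <- function() {
  tibble::tibble(chrom = character(), start = double(), end = double(),
                 nadir = double(), min_smooth = double(), n_points = integer())
}

#' Runs of homozygosity
#'
#' Maximal runs of consecutive called sites containing at most `max_het`
#' heterozygous calls, retained when they span at least `min_sites` sites and
#' `min_len_bp`; overlapping retained runs are merged. The length thresholds
#' are package defaults (the analysis they support does not prescribe any).
#'
#' @param ds A [genotype_dataset()].
#' @param sample Sample id.
#' @param min_sites Minimum called sites per run.
#' @param max_het Maximum heterozygous calls per run.
#' @param min_len_bp Minimum physical span (bp).
#' @return Tibble: `chrom`, `start`, `end` (1-based inclusive site
#'   positions), `n_sites`, `n_het`.
#' @export
roh_scan <- function(ds, sample, min_sites = 50, max_het = 1,
                     min_len_bp = 1e5) {
  col <- match(sample, ds$samples$sample)
  if (is.na(col)) stop("unknown sample: ", sample, call. = FALSE)
  g <- ds$gt[, col]
  out <- list()
  for (ch in unique(ds$sites$chrom)) {
    sel <- which(ds$sites$chrom == ch & !is.na(g))
    if (length(sel) < min_sites) next
    pos <- ds$sites$pos[sel]
    het <- which(g[sel] == 1L)
    k <- max_het
    # maximal candidate runs delimited by the (i)th and (i+k+1)th hets
    bounds <- c(0L, het, rep(length(sel) + 1L, k + 1))
    n_h <- length(het)
    cand <- lapply(0:(n_h), function(i) {
      lo <- bounds[i + 1] + 1L
      hi <- bounds[i + k + 2] - 1L
      if (hi < lo) return(NULL)
      c(lo, hi)
    })
    cand <- unique(Filter(Negate(is.null), cand))
    runs <- dplyr::bind_rows(lapply(cand, function(b) {
      n_run <- b[2] - b[1] + 1L
      len <- pos[b[2]] - pos[b[1]] + 1
      if (n_run < min_sites || len < min_len_bp) return(NULL)
      tibble::tibble(chrom = ch, start = pos[b[1]], end = pos[b[2]],
                     n_sites = n_run,
                     n_het = sum(g[sel[b[1]:b[2]]] == 1L))
    }))
    if (nrow(runs) == 0 || is.null(runs)) next
    runs <- dplyr::arrange(runs, .data$start)
    merged <- runs[1, ]
    for (i in seq_len(nrow(runs))[-1]) {
      last <- nrow(merged)
      if (runs$start[i] <= merged$end[last]) {
        merged$end[last] <- max(merged$end[last], runs$end[i])
        merged$n_sites[last] <- sum(pos >= merged$start[last] &
                                      pos <= merged$end[last])
        merged$n_het[last] <- sum(g[sel] == 1L & pos >= merged$start[last] &
                                    pos <= merged$end[last])
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
    out[[ch]] <- merged
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), n_sites = integer(),
                          n_het = integer())
  }
  res
}

#' Iterative regional haplotype inference
#'
#' Resolves the two haplotypes of each accession over a region's sites by
#' iterated subtraction from a growing panel, starting from a reference
#' haplotype and from accessions homozygous at every region site: for each
#' unresolved accession, if subtracting exactly one distinct panel haplotype
#' from its genotypes yields a site-wise consistent complement, both
#' haplotypes are assigned and the complement joins the panel; iteration
#' stops at a fixpoint. Accessions with zero or multiple distinct consistent
#' resolutions (or missing calls in the region) stay unresolved — the
#' inference never guesses.
#'
#' @param ds A [genotype_dataset()].
#' @param region List or one-row tibble with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param reference_hap Integer vector (0/1 per region site) of the reference
#'   haplotype.
#' @return A `haplotype_panel`: list with `haplotypes` (tibble: `hap_id`,
#'   `alleles` string, `count`, `freq`), `assignments` (tibble: `sample`,
#'   `hap1`, `hap2`, `resolved`), `diplotype_freq` (tibble over resolved
#'   accessions), `sites` (region site positions).
#' @export
infer_region_haplotypes <- function(ds, region, reference_hap) {
  idx <- which(ds$sites$chrom == region$chrom &
                 ds$sites$pos - 1 >= region$start &
                 ds$sites$pos - 1 < region$end)
  if (!length(idx)) stop("region overlaps no sites", call. = FALSE)
  if (length(reference_hap) != length(idx)) {
    stop("reference_hap must cover the region's ", length(idx), " sites",
         call. = FALSE)
  }
  G <- ds$gt[idx, , drop = FALSE]
  m <- ncol(G)
  consistent_with_ref <- vapply(seq_len(m), function(j) {
    g <- G[, j]
    !anyNA(g) && all(g - reference_hap >= 0 & g - reference_hap <= 1)
  }, logical(1))
  if (!any(consistent_with_ref)) {
    stop("reference haplotype is inconsistent with every accession in the region",
         call. = FALSE)
  }
  panel <- list(as.integer(reference_hap))
  hap_key <- function(h) paste(h, collapse = "")
  keys <- hap_key(panel[[1]])
  add_hap <- function(h) {
    k <- hap_key(h)
    pos <- match(k, keys)
    if (is.na(pos)) {
      panel[[length(panel) + 1]] <<- as.integer(h)
      keys <<- c(keys, k)
      pos <- length(panel)
    }
    pos
  }
  hap1 <- rep(NA_integer_, m); hap2 <- rep(NA_integer_, m)
  complete <- colSums(is.na(G)) == 0
  # homozygous-everywhere accessions seed the panel
  for (j in which(complete)) {
    g <- G[, j]
    if (all(g %in% c(0L, 2L))) {
      h <- add_hap(g %/% 2L)
      hap1[j] <- h; hap2[j] <- h
    }
  }
  repeat {
    changed <- FALSE
    for (j in which(is.na(hap1) & complete)) {
      g <- G[, j]
      pairs <- list()
      pair_keys <- character()
      for (hidx in seq_along(panel)) {
        comp <- g - panel[[hidx]]
        if (all(comp >= 0L & comp <= 1L)) {
          pk <- paste(sort(c(keys[hidx], hap_key(comp))), collapse = "/")
          if (!pk %in% pair_keys) {
            pairs[[length(pairs) + 1]] <- list(h = hidx, comp = comp)
            pair_keys <- c(pair_keys, pk)
          }
        }
      }
      if (length(pairs) == 1) {
        h2 <- add_hap(pairs[[1]]$comp)
        hap1[j] <- pairs[[1]]$h; hap2[j] <- h2
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  resolved <- !is.na(hap1)
  counts <- tabulate(c(hap1[resolved], hap2[resolved]), nbins = length(panel))
  haplotypes <- tibble::tibble(
    hap_id = sprintf("H%d", seq_along(panel)),
    alleles = vapply(panel, hap_key, character(1)),
    count = counts,
    freq = if (sum(counts) > 0) counts / sum(counts) else NA_real_)
  assignments <- tibble::tibble(
    sample = ds$samples$sample,
    hap1 = ifelse(resolved, sprintf("H%d", hap1), NA_character_),
    hap2 = ifelse(resolved, sprintf("H%d", hap2), NA_character_),
    resolved = resolved)
  diplo <- assignments[assignments$resolved, ]
  dkey <- purrr::map2_chr(diplo$hap1, diplo$hap2,
                          function(a, b) paste(sort(c(a, b)), collapse = "/"))
  diplotype_freq <- dplyr::count(tibble::tibble(diplotype = dkey),
                                 .data$diplotype, name = "count")
  diplotype_freq$freq <- diplotype_freq$count / sum(diplotype_freq$count)
  structure(
    list(region = tibble::as_tibble(region[c("chrom", "start", "end")]),
         sites = ds$sites$pos[idx],
         haplotypes = haplotypes, assignments = assignments,
         diplotype_freq = diplotype_freq),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d sites, %d haplotypes, %d/%d accessions resolved\n",
              length(x$sites), nrow(x$haplotypes),
              sum(x$assignments$resolved), nrow(x$assignments)))
  print(x$haplotypes)
  invisible(x)
}

#' @export
tidy.haplotype_panel <- function(x, ...) x$haplotypes

#' @export
glance.haplotype_panel <- function(x, ...) {
  tibble::tibble(n_sites = length(x$sites),
                 n_haplotypes = nrow(x$haplotypes),
                 n_resolved = sum(x$assignments$resolved),
                 n_accessions = nrow(x$assignments))
}
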