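#' Repeat masks
#'
#' A repeat mask is a set of genomic intervals of repetitive DNA, stored
#' 0-based half-open (BED convention). `repeat_mask()` normalizes arbitrary
#' input intervals: sorts them, merges overlaps and abutting runs, and drops
#' empty intervals, so downstream code can assume disjoint sorted intervals.
#'
#' @param intervals Tibble (or data frame) with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return A tibble of class `repeat_mask` with non-overlapping sorted
#'   intervals.
#' @export
repeat_mask <- function(intervals = NULL) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    out <- tibble::tibble(chrom = character(), start = double(), end = double())
    class(out) <- c("repeat_mask", class(out))
    return(out)
  }
  x <- tibble::as_tibble(intervals)[, c("chrom", "start", "end")]
  x <- x[x$end > x$start, ]
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  merged <- dplyr::group_modify(dplyr::group_by(x, .data$chrom), function(d, key) {
    s <- d$start; e <- d$end
    keep_s <- s[1]; out_s <- double(); out_e <- double()
    cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- s[i]; cur_e <- e[i]
      } else {
        cur_e <- max(cur_e, e[i])
      }
    }
    tibble::tibble(start = c(out_s, keep_s), end = c(out_e, cur_e))
  })
  out <- dplyr::ungroup(merged)
  class(out) <- c("repeat_mask", class(out))
  out
}

#' Total masked bp overlapping an interval
#'
#' @param mask A [repeat_mask()].
#' @param chrom Chromosome id.
#' @param start,end Interval bounds, 0-based half-open (vectorized).
#' @return Numeric vector of masked bp in each query interval.
#' @export
masked_bp <- function(mask, chrom, start, end) {
  m <- mask[mask$chrom == chrom, ]
  if (nrow(m) == 0) return(rep(0, length(start)))
  # coverage function: cumulative masked bp strictly before position x
  cum <- c(0, cumsum(m$end - m$start))
  cov_at <- function(x) {
    i <- findInterval(x, m$start)
    base <- cum[i + 1]
    inside <- i >= 1 & x < m$end[pmax(i, 1)]
    base[inside] <- cum[i[inside]] + (x[inside] - m$start[i[inside]])
    base
  }
  cov_at(end) - cov_at(start)
}

#' Flag sites that fall inside a repeat mask
#'
#' @param mask A [repeat_mask()].
#' @param chrom,pos Site coordinates (`pos` 1-based).
#' @return Logical vector.
#' @export
sites_in_mask <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    m <- mask[mask$chrom == ch, ]
    sel <- chrom == ch
    if (nrow(m) == 0) next
    p0 <- pos[sel] - 1
    i <- findInterval(p0, m$start)
    out[sel] <- i >= 1 & p0 < m$end[pmax(i, 1)]
  }
  out
}

#' Segment a genome into analysis windows
#'
#' Two windowing schemes are supported. `"nonrep_fixed"` accumulates unmasked
#' (non-repetitive) bases left to right and closes a window at the base where
#' the running total reaches `w`; windows therefore have variable physical
#' span but a fixed non-repetitive content (the scheme used for genome-wide
#' window counts such as 100 kb of non-repetitive DNA per window). The
#' trailing remainder of each chromosome is emitted as a final short window
#' flagged `partial` and is excluded from scans by default. `"sliding"`
#' produces fixed-span windows advanced by `step`, each annotated with its
#' non-repetitive bp.
#'
#' @param mask A [repeat_mask()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param mode `"nonrep_fixed"` or `"sliding"`.
#' @param w Target non-repetitive bp per window (nonrep_fixed mode).
#' @param span,step Window span and step in bp (sliding mode).
#' @return A tibble of class `window_set` with columns `index`, `chrom`,
#'   `start`, `end` (0-based half-open), `nonrep_bp`, `partial`.
#' @export
make_windows <- function(mask, chrom_lengths, mode = c("nonrep_fixed", "sliding"),
                         w = 1e5, span = 1e5, step = 2.5e4) {
  mode <- match.arg(mode)
  miss <- setdiff(unique(mask$chrom), names(chrom_lengths))
  if (length(miss)) {
    stop("chromosome(s) in mask absent from lengths: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  res <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    if (mode == "nonrep_fixed") {
      stopifnot(w > 0)
      m <- mask[mask$chrom == ch, ]
      # unmasked segments covering [0, len)
      bnd <- c(0, as.vector(rbind(m$start, m$end)), len)
      seg_s <- bnd[seq(1, length(bnd) - 1, by = 2)]
      seg_e <- bnd[seq(2, length(bnd), by = 2)]
      ok <- seg_e > seg_s
      seg_s <- seg_s[ok]; seg_e <- seg_e[ok]
      seg_len <- seg_e - seg_s
      total <- sum(seg_len)
      n_full <- floor(total / w)
      cum <- cumsum(seg_len)
      if (n_full > 0) {
        targets <- w * seq_len(n_full)
        # segment in which the target-th unmasked base falls
        seg_i <- findInterval(targets - 1e-9, c(0, cum))
        cut <- seg_s[seg_i] + (targets - c(0, cum)[seg_i])
        starts <- c(0, cut[-n_full])
        ends <- cut
        win <- tibble::tibble(chrom = ch, start = starts, end = ends,
                              nonrep_bp = w, partial = FALSE)
      } else {
        win <- tibble::tibble(chrom = character(), start = double(),
                              end = double(), nonrep_bp = double(),
                              partial = logical())
      }
      rem <- total - n_full * w
      last_end <- if (n_full > 0) win$end[n_full] else 0
      if (last_end < len) {
        win <- dplyr::bind_rows(win, tibble::tibble(
          chrom = ch, start = last_end, end = len,
          nonrep_bp = rem, partial = TRUE))
      }
    } else {
      stopifnot(step <= span, span > 0)
      if (len < span) {
        win <- tibble::tibble(chrom = character(), start = double(),
                              end = double(), nonrep_bp = double(),
                              partial = logical())
      } else {
        starts <- seq(0, len - span, by = step)
        ends <- starts + span
        win <- tibble::tibble(
          chrom = ch, start = starts, end = ends,
          nonrep_bp = (ends - starts) - masked_bp(mask, ch, starts, ends),
          partial = FALSE)
      }
    }
    res[[ch]] <- win
  }
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(out, index = dplyr::row_number(), .before = 1)
  attr(out, "mode") <- mode
  attr(out, "params") <- if (mode == "nonrep_fixed") list(w = w) else
    list(span = span, step = step)
  attr(out, "chrom_lengths") <- chrom_lengths
  class(out) <- c("window_set", class(out))
  out
}

#' Map sites to windows
#'
#' Every unmasked site maps to exactly one `nonrep_fixed` window, or to all
#' sliding windows that overlap it. Masked sites map to none.
#'
#' @param ds A [genotype_dataset()].
#' @param ws A [window_set][make_windows()].
#' @return Tibble with columns `site` (row index in `ds$sites`) and `window`
#'   (window index); one row per (site, window) assignment. The number of
#'   unassignable unmasked sites is stored in attribute `n_unassigned`.
#' @export
assign_sites <- function(ds, ws) {
  mode <- attr(ws, "mode")
  keep <- which(!ds$sites$masked)
  chrom <- ds$sites$chrom[keep]
  pos0 <- ds$sites$pos[keep] - 1
  rows <- list()
  unassigned <- 0L
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    si <- keep[sel]
    p0 <- pos0[sel]
    wch <- ws[ws$chrom == ch, ]
    if (nrow(wch) == 0) {
      unassigned <- unassigned + length(si)
      next
    }
    if (mode == "nonrep_fixed") {
      i <- findInterval(p0, wch$start)
      inside <- i >= 1 & p0 < wch$end[pmax(i, 1)]
      unassigned <- unassigned + sum(!inside)
      rows[[ch]] <- tibble::tibble(site = si[inside],
                                   window = wch$index[i[inside]])
    } else {
      span <- attr(ws, "params")$span
      step <- attr(ws, "params")$step
      n_win <- nrow(wch)
      # window j (1-based within chrom) covers [ (j-1)*step, (j-1)*step + span )
      j_hi <- pmin(floor(p0 / step) + 1, n_win)
      j_lo <- pmax(ceiling((p0 - span) / step + 1e-9) + 1, 1)
      ok <- j_hi >= j_lo
      unassigned <- unassigned + sum(!ok)
      cnt <- pmax(j_hi - j_lo + 1, 0)
      rows[[ch]] <- tibble::tibble(
        site = rep(si, cnt),
        window = wch$index[unlist(purrr::map2(j_lo[ok], j_hi[ok], seq),
                                  use.names = FALSE)])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::arrange(out, .data$site, .data$window)
  attr(out, "n_unassigned") <- unassigned
  out
}

#' Read / write interval files
#'
#' `read_repeat_mask()` reads a BED3 file into a [repeat_mask()];
#' `write_windows_bed()` serializes a window set as BED4 (name = window
#' index) and `read_windows_bed()` restores the intervals.
#'
#' @param path File path.
#' @return `read_repeat_mask()` a [repeat_mask()]; `read_windows_bed()` a
#'   tibble of windows.
#' @export
read_repeat_mask <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cdd", progress = FALSE)
  repeat_mask(bed)
}

#' @rdname read_repeat_mask
#' @param mask A [repeat_mask()] to serialize.
#' @export
write_repeat_mask <- function(mask, path) {
  readr::write_tsv(mask[, c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname read_repeat_mask
#' @param ws A [window_set][make_windows()].
#' @export
write_windows_bed <- function(ws, path) {
  out <- tibble::tibble(chrom = ws$chrom, start = ws$start, end = ws$end,
                        name = ws$index)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname read_repeat_mask
#' @export
read_windows_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "index"),
                  col_types = "cddi", progress = FALSE)
}
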