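#' Plot methods
#'
#' `autoplot()` methods render the package's result objects with ggplot2:
#' an introgression scan as per-window adjusted f_d dots along the genome, a
#' diversity track as plotted block means (dots) with the smoothing spline
#' (line), an IBD profile as per-window IBD states, and an ASE result as
#' imbalance ratio against the combined Z.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name vitipop-autoplot
NULL

#' @rdname vitipop-autoplot
#' @export
autoplot.introgression_scan <- function(object, ...) {
  w <- object$windows
  w$mid <- (w$start + w$end) / 2
  ggplot2::ggplot(w[!is.na(w$fd), ],
                  ggplot2::aes(x = .data$mid / 1e6, y = .data$fd)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6, colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(f[d]),
                  title = "Windowed adjusted f_d") +
    ggplot2::theme_minimal()
}

#' @rdname vitipop-autoplot
#' @export
autoplot.diversity_track <- function(object, ...) {
  p <- object$points
  ggplot2::ggplot(p, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$H), colour = "steelblue",
                        size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "black") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "haplotype diversity") +
    ggplot2::theme_minimal()
}

#' @rdname vitipop-autoplot
#' @export
autoplot.ibd_profile <- function(object, ...) {
  w <- object$windows[!is.na(object$windows$state), ]
  w$mid <- (w$start + w$end) / 2
  ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e6, y = 1,
                                  fill = factor(.data$state))) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "left") +
    ggplot2::scale_fill_manual(values = c(`0` = "firebrick", `1` = "gold",
                                          `2` = "forestgreen"),
                               name = "IBD state") +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = paste(object$pair, collapse = " - ")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname vitipop-autoplot
#' @export
autoplot.ase_result <- function(object, ...) {
  ggplot2::ggplot(object[!object$undefined, ],
                  ggplot2::aes(x = .data$r, y = .data$z,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "allelic imbalance ratio", y = "Stouffer Z") +
    ggplot2::theme_minimal()
}

#' Plot an unfolded site frequency spectrum
#'
#' @param sfs A tibble from [unfolded_sfs()].
#' @return A ggplot object.
#' @export
plot_sfs <- function(sfs) {
  seg <- sfs[sfs$k > 0 & sfs$k < max(sfs$k), ]
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$k, y = .data$n_sites)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "derived allele copies", y = "sites",
                  title = "Unfolded site frequency spectrum") +
    ggplot2::theme_minimal()
}
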