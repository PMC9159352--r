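#' Manhattan-style plot of a gradient scan statistic
#'
#' One panel per population pair, signal against genomic position, with
#' pair-1 top-tail units and gradient-passing units highlighted.
#'
#' @param scan a [sweep_scan()] result.
#' @param statistic `"pi_ratio"`, `"fst"` or `"xpehh"`.
#' @return a ggplot object.
#' @export
plot_scan <- function(scan, statistic = c("fst", "pi_ratio", "xpehh")) {
  statistic <- match.arg(statistic)
  tbl <- scan[[statistic]]
  if (is.null(tbl)) stop("statistic ", statistic, " was not computed")
  x <- if ("pos" %in% names(tbl)) tbl$pos else (tbl$start + tbl$end) / 2
  long <- purrr::map_dfr(1:3, function(k) {
    tibble::tibble(pos = x, pair = paste("pair", k),
                   signal = tbl[[paste0("signal_", k)]],
                   selected = tbl$selected_pair1,
                   gradient = tbl$gradient_pass)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = pos / 1e6, y = signal)) +
    ggplot2::geom_point(ggplot2::aes(colour = gradient, shape = selected),
                        size = 1, alpha = 0.8) +
    ggplot2::facet_wrap(~pair, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = statistic,
                  colour = "gradient pass", shape = "pair-1 top tail") +
    ggplot2::theme_minimal()
}

#' Plot an LD decay curve
#'
#' @param decay tibble from [ld_decay()].
#' @return a ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(x = bin_mid / 1000, y = mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' @describeIn gt_pca scatter of the first two PCs, coloured by group when
#'   present, with variance fractions in the axis labels.
#' @param object a `gt_pca`.
#' @param ... unused.
#' @export
autoplot.gt_pca <- function(object, ...) {
  sc <- object$scores
  ve <- object$var_explained
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = PC1, y = PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.2f%%)", 100 * ifelse(length(ve) > 1, ve[2], 0))) +
    ggplot2::theme_minimal()
  if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = group))
  } else {
    p + ggplot2::geom_point()
  }
}

#' @describeIn ehhs_profile plot the EHHS decay around the core.
#' @param object an `ehh_profile`.
#' @param ... unused.
#' @export
autoplot.ehh_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = distance / 1000, y = ehhs)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "distance from core (kb)", y = "EHHS") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
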