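# ggplot2 figures for the evaluation outputs.

#' MAF spectrum of polymorphic SNPs
#'
#' Histogram of observed minor allele frequencies, the standard panel
#' figure for an array evaluation.
#'
#' @param classification A [classify_snps()] result.
#' @param binwidth MAF bin width.
#' @return A ggplot object.
#' @export
plot_maf_spectrum <- function(classification, binwidth = 0.05) {
  df <- tibble::as_tibble(unclass(classification))
  df <- df[df$class == "polymorphic" & !is.na(df$maf), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::scale_x_continuous(limits = c(0, 0.5)) +
    ggplot2::labs(x = "Minor allele frequency", y = "Polymorphic SNPs") +
    ggplot2::theme_minimal()
}

#' Export MAF histogram bin counts
#'
#' Figure-ready CSV companion of [plot_maf_spectrum()].
#'
#' @inheritParams plot_maf_spectrum
#' @return Tibble `bin_low`, `bin_high`, `n`.
#' @export
maf_bin_counts <- function(classification, binwidth = 0.05) {
  maf <- classification$maf[classification$class == "polymorphic"]
  breaks <- seq(0, 0.5 + binwidth, by = binwidth)
  bins <- cut(maf, breaks = breaks, right = FALSE)
  tibble::tibble(
    bin_low = head(breaks, -1),
    bin_high = breaks[-1],
    n = as.integer(table(bins))
  )
}

#' Gap-size distribution of an array design
#'
#' @param design Tibble with `chrom`, `pos`.
#' @param binwidth_kb Histogram bin width in kb.
#' @return A ggplot object.
#' @export
plot_gap_histogram <- function(design, binwidth_kb = 5) {
  gaps <- design |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(gap_kb = diff(sort(.data$pos)) / 1000)
  ggplot2::ggplot(gaps, ggplot2::aes(x = .data$gap_kb)) +
    ggplot2::geom_histogram(binwidth = binwidth_kb, boundary = 0,
                            fill = "darkorange", colour = "white") +
    ggplot2::labs(x = "Gap between successive SNPs (kb)", y = "Gaps") +
    ggplot2::theme_minimal()
}

#' Filtering funnel plot
#'
#' @param funnel Stage-count log (`stage`, `rule`, `remaining`), e.g.
#'   `run_pipeline()$funnel`.
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  funnel <- dplyr::mutate(funnel,
                          step = factor(paste(.data$stage, .data$rule,
                                              sep = ": "),
                                        levels = paste(.data$stage,
                                                       .data$rule,
                                                       sep = ": ")))
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$step,
                                       y = .data$remaining)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "SNPs remaining") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.snp_classification <- function(object, ...) {
  plot_maf_spectrum(object, ...)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gap_stats <- function(object, ...) {
  df <- object[object$chrom != "total", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom,
                                   y = .data$avg_gap_kb)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Average gap (kb)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
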