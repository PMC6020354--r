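# ggplot2 displays for the main result types.

#' Volcano plot of a divergence test
#'
#' @param result a `divergence_result` tibble.
#' @param comparison optional comparison label to restrict to.
#' @return A ggplot.
#' @export
plot_volcano <- function(result, comparison = NULL) {
  if (!is.null(comparison))
    result <- result[result$comparison == comparison, ]
  ggplot2::ggplot(result,
                  ggplot2::aes(x = .data$effect,
                               y = -log10(.data$p_nominal),
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#2166ac")) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log2 ratio", y = "-log10 p",
                  colour = "FWER <= cutoff") +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object,... passed through to [plot_volcano()].
#' @export
autoplot.divergence_result <- function(object, ...) plot_volcano(object, ...)

#' Periodicity profile display
#'
#' Bars of relative footprint enrichment by position, coloured by codon
#' frame.
#'
#' @param object a `periodicity_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.periodicity_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$enrichment,
                               fill = factor(.data$frame))) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "position relative to initiation site (P-site shifted)",
                  y = "relative enrichment", fill = "frame") +
    ggplot2::theme_minimal()
}

#' Propagation curve display
#'
#' r^2 between protein and occupancy divergence by protein-FDR cutoff, with
#' and without transcript divergence regressed out.
#'
#' @param object a `propagation_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.propagation_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("r2_raw", "r2_rna_adjusted"),
                              names_to = "adjustment", values_to = "r2")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$cutoff), y = .data$r2,
                                     colour = .data$adjustment,
                                     group = .data$adjustment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "protein divergence FDR cutoff",
                  y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of p-value sets against uniform
#'
#' The canonical display for comparing how often different tests reject:
#' observed -log10 p against the uniform expectation.
#'
#' @param p_list named list of p-value vectors.
#' @return A ggplot.
#' @export
plot_pvalue_qq <- function(p_list) {
  df <- dplyr::bind_rows(lapply(names(p_list), function(nm) {
    p <- sort(p_list[[nm]][!is.na(p_list[[nm]])])
    tibble(test = nm,
           expected = -log10((seq_along(p) - 0.5) / length(p)),
           observed = -log10(p))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$test)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = "expected -log10 p", y = "observed -log10 p") +
    ggplot2::theme_minimal()
}
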