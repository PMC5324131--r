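#' Funnel plot of the identification cascade
#'
#' @param object A `lnc_cascade`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_cascade <- function(object, ...) {
  dat <- object$report |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts remaining",
                  title = "lncRNA identification funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Volcano plot of a differential-expression table
#'
#' x axis is log2(FPKM WT / FPKM MT), so points on the left are higher in
#' the mutant.
#'
#' @param object A `lnc_de`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lnc_de <- function(object, ...) {
  dat <- filter(tidy(object), .data$call != "filtered")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$p_value),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up_in_MT = "#d1495b",
                                            down_in_MT = "#00798c",
                                            not_significant = "grey70")) +
    ggplot2::labs(x = "log2 FC (WT / MT)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of lncRNA positional classes
#'
#' @param classes Output of [classify_position()].
#' @return A ggplot.
#' @export
plot_class_distribution <- function(classes) {
  dat <- classes |>
    count(positional_class = factor(.data$positional_class,
                                    levels = c("intergenic", "intragenic",
                                               "antisense"))) |>
    mutate(fraction = .data$n / sum(.data$n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$positional_class,
                                    y = .data$fraction)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of lncRNAs") +
    ggplot2::theme_minimal()
}

#' Genomic density profile of lncRNAs and coding genes
#'
#' @param density Output of [density_profile()] (with a `group` column).
#' @return A ggplot.
#' @export
plot_density_profile <- function(density) {
  ggplot2::ggplot(density,
                  ggplot2::aes(x = .data$bin_start / 1e6, y = .data$n,
                               fill = if ("group" %in% names(density))
                                 .data$group else NULL)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "features per bin",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Length and exon-count histograms (lncRNA vs coding)
#'
#' @param structure Output of [structure_summary()].
#' @return A ggplot.
#' @export
plot_structure_summary <- function(structure) {
  dat <- structure |>
    mutate(bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                    fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
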