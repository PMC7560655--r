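#' Plot a copy-number segment profile
#'
#' Segments drawn as horizontal bars along each chromosome, faceted per
#' sample; LOH segments highlighted. Dashed guides mark the diploid
#' level and the 2.3 segmental-gain threshold.
#'
#' @param profile Segment profile tibble.
#' @param samples Optional subset of sample ids.
#' @return A ggplot object.
#' @export
plot_copy_profile <- function(profile, samples = NULL) {
  check_profile(profile)
  if (!is.null(samples)) profile <- profile |> filter(.data$sample %in% samples)
  chroms <- unique(profile$chrom)
  profile <- profile |> mutate(chrom = factor(.data$chrom, levels = chroms))
  ggplot2::ggplot(profile) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                                       y = .data$copy, yend = .data$copy,
                                       colour = .data$loh), linewidth = 1.2) +
    ggplot2::geom_hline(yintercept = c(2, 2.3), linetype = "dashed",
                        colour = "grey50", linewidth = 0.3) +
    ggplot2::facet_grid(sample ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25", `TRUE` = "firebrick"),
                                 name = "LOH") +
    ggplot2::labs(x = "position (Mb)", y = "absolute copy number") +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0, "pt"),
                   axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot a 96-class mutation spectrum
#'
#' The classic six-panel trinucleotide barplot, one facet per
#' substitution type.
#'
#' @param spectrum Long spectrum tibble from [build_spectrum()].
#' @param samples Optional subset of sample ids.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, samples = NULL) {
  if (!is.null(samples)) spectrum <- spectrum |> filter(.data$sample %in% samples)
  spectrum <- spectrum |>
    mutate(class = factor(.data$class, levels = sbs96_classes()),
           substitution = sub(".*\\[(.+)\\].*", "\\1", .data$class))
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$class, y = .data$count,
                                         fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(sample ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "SNVs") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot a signature refit: observed vs reconstructed spectrum
#'
#' @param object A `sig_fit` from [refit_exposures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sig_fit <- function(object, ...) {
  df <- tibble(class = factor(names(object$observed), levels = sbs96_classes()),
               observed = as.numeric(object$observed),
               reconstructed = as.numeric(object$fitted)) |>
    tidyr::pivot_longer(c("observed", "reconstructed"),
                        names_to = "which", values_to = "count") |>
    mutate(substitution = sub(".*\\[(.+)\\].*", "\\1", .data$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "SNVs",
                  subtitle = sprintf("reconstruction cosine %.3f", object$cosine)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot diagnosis-age empirical cumulative distributions
#'
#' @param test Result of [age_distribution_test()].
#' @return A ggplot object.
#' @export
plot_age_ecdf <- function(test) {
  ggplot2::ggplot(test$ecdf,
                  ggplot2::aes(x = .data$age_years,
                               y = .data$fraction_at_or_before,
                               colour = .data$set)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "age at diagnosis (years)",
                  y = "fraction diagnosed at or before") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
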