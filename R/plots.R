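# ggplot2 figures: 96-category spectrum bar chart and penetrance plot.

SBS_CLASS_COLORS <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
                      "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")

#' Bar chart of a 96-category mutational profile
#'
#' Category fractions in the fixed order, faceted by substitution class
#' with the conventional class colours.
#'
#' @param p a [profile96()].
#' @return a ggplot object.
#' @export
plot_profile96 <- function(p) {
  stopifnot(inherits(p, "Profile96"))
  cats <- names(p$counts)
  df <- data.frame(
    category = factor(cats, levels = cats),
    context = paste0(substr(cats, 1, 1), substr(cats, 3, 3), substr(cats, 7, 7)),
    class = factor(sub("^.\\[(.+)\\].$", "\\1", cats), levels = SBS_CLASSES),
    fraction = as.numeric(profile_fractions(p))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::facet_grid(. ~ class, scales = "free_x") +
    ggplot2::scale_fill_manual(values = SBS_CLASS_COLORS, guide = "none") +
    ggplot2::scale_x_discrete(labels = df$context) +
    ggplot2::labs(title = sprintf("%s (n = %d)", p$label, p$n),
                  x = NULL, y = "fraction of mutations") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5, family = "mono"))
}

#' Penetrance plot
#'
#' Shared copy-number aberrations across samples: per genomic interval the
#' fraction of samples with a gain (up) or loss (down).
#'
#' @param pen a [penetrance()] table.
#' @return a ggplot object.
#' @export
plot_penetrance <- function(pen) {
  stopifnot(inherits(pen, "PenetranceTable"))
  df <- as.data.frame(pen)
  df$signed <- ifelse(df$direction == "gain", df$fraction, -df$fraction)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = pmin(0, .data$signed),
                                    ymax = pmax(0, .data$signed),
                                    fill = .data$direction)) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(gain = "#2166AC", loss = "#B2182B")) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", abs(v) * 100),
                                limits = c(-1, 1)) +
    ggplot2::labs(x = "genomic position", y = "samples sharing aberration") +
    ggplot2::theme_minimal(base_size = 9)
}
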