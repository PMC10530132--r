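#' Pareto chart of screening effect shares
#'
#' Bars show each real factor's share of the summed absolute effects, ordered
#' by size and colored by significance against the dummy-factor F test.
#'
#' @param object A `pb_screen` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pb_screen
#' @export
autoplot.pb_screen <- function(object, ...) {
  tab <- object$table[!object$table$is_dummy, ]
  tab$factor <- stats::reorder(tab$factor, -tab$share)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$factor, y = .data$share,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#2c7fb8"),
                               name = sprintf("F > %.0f", object$f_critical)) +
    ggplot2::labs(x = NULL, y = "Share of summed |effect| (%)",
                  title = "Plackett-Burman effect shares") +
    ggplot2::theme_minimal()
}

#' Main-effect profile of a Taguchi fit
#'
#' Mean S/N ratio at each factor level, one panel per factor, with the grand
#' mean as a dashed reference and the chosen optimum highlighted.
#'
#' @param object A `taguchi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot taguchi_fit
#' @export
autoplot.taguchi_fit <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$level, y = .data$sn_mean)) +
    ggplot2::geom_hline(yintercept = object$grand_mean, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$optimal), size = 2.5) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "#d95f02"),
                                name = "optimal level") +
    ggplot2::scale_x_continuous(breaks = sort(unique(tab$level))) +
    ggplot2::facet_wrap(~factor, nrow = 1) +
    ggplot2::labs(x = "Level", y = "Mean S/N ratio (dB)",
                  title = sprintf("Level means (optimum %s, predicted S/N %.2f dB)",
                                  object$optimum_label, object$predicted_sn)) +
    ggplot2::theme_minimal()
}

#' Box plot of a pellet-diameter distribution
#'
#' The five-number-summary box plot of Feret diameters, whiskers to the most
#' extreme points within 1.5 IQR of the box, outliers beyond them as open
#' circles, and the mean marked with a cross.
#'
#' @param object A `morph_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot morph_summary
#' @export
autoplot.morph_summary <- function(object, ...) {
  df <- tibble(feret = object$diameters)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$feret)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1, width = 0.4) +
    ggplot2::annotate("point", x = 1, y = object$feret_mean, shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "Feret diameter",
                  title = sprintf("Pellet diameters (n = %d, CU = %.2f)",
                                  object$count, object$cu)) +
    ggplot2::theme_minimal()
}
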