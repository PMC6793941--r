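#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot couple-level IPV prevalence
#'
#' Bar chart of the six taxonomy categories or the overlap rollups, with
#' percentage labels.
#'
#' @param object,x an [ipv_prevalence()] object.
#' @param rollups plot the overlap rollups instead of the six categories.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ipv_prevalence <- function(object, rollups = FALSE, ...) {
  keep <- if (rollups) .rollup_levels else .category_levels
  dat <- dplyr::filter(tidy(object), .data$measure %in% keep) %>%
    dplyr::mutate(measure = factor(.data$measure, levels = keep))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$measure, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of couples",
                  title = "Past-year IPV prevalence at the couple level",
                  subtitle = sprintf("N = %d couples with at least one report",
                                     attr(object, "denominator"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.ipv_prevalence
#' @export
plot_prevalence <- function(x, rollups = FALSE) autoplot(x, rollups = rollups)

#' Plot the direction split of one IPV type
#'
#' @param object,x an [direction_table()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ipv_direction_table <- function(object, ...) {
  ggplot2::ggplot(object$directions,
                  ggplot2::aes(x = .data$direction, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of type-positive couples",
                  title = .type_titles[[object$ipv_type]],
                  subtitle = sprintf("n = %d couples", object$n_type)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ipv_direction_table
#' @export
plot_direction <- function(x) autoplot(x)

#' Plot an intradyadic concordance 2x2 table
#'
#' Tile plot of the cross-tabulation of the two informants' any-occurrence
#' indicators with the percent agreement in the title.
#'
#' @param object,x an [concordance()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ipv_concordance <- function(object, ...) {
  dat <- dplyr::mutate(object$table,
                       woman_report = ifelse(.data$woman_report, "yes", "no"),
                       partner_report = ifelse(.data$partner_report, "yes", "no"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$woman_report,
                                    y = .data$partner_report,
                                    fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "grey10",
                                 guide = "none") +
    ggplot2::labs(x = "pregnant woman reports", y = "partner reports",
                  title = sprintf("Concordance, %s physical IPV",
                                  object$direction),
                  subtitle = sprintf("agreement %.1f%% (n = %d dual-report couples)",
                                     object$agreement, object$n_dual)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ipv_concordance
#' @export
plot_concordance <- function(x) autoplot(x)
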