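# ggplot2 figures for the main result types.

#' Lorenz curve plot
#'
#' One curve per named count distribution, against the line of equality.
#'
#' @param ... Named non-negative count vectors (or a single unnamed one).
#' @return A ggplot object.
#' @examples
#' plot_lorenz(all_papers = c(100, 5, 3, 1), sdars = c(4, 3, 3, 2))
#' @export
plot_lorenz <- function(...) {
  counts <- list(...)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    names(counts) <- paste0("series", seq_along(counts))
  }
  df <- bind_rows(lapply(names(counts), function(nm) {
    mutate(lorenz_curve(counts[[nm]]), series = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$p, .data$share,
                                   colour = .data$series)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Cumulative fraction of entities (sorted ascending)",
                  y = "Cumulative share of output", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname concentration
#' @param object A `concentration` object.
#' @method autoplot concentration
#' @export
autoplot.concentration <- function(object, ...) {
  plot_lorenz(counts = object$x) +
    ggplot2::labs(subtitle = sprintf("Gini = %.3f over %d entities",
                                     object$gini, object$n)) +
    ggplot2::theme(legend.position = "none")
}

#' Decay curve plot
#'
#' Accessible fraction by publication year, from [decay_curve()].
#'
#' @param curve Tibble with `pub_year` and `fraction`.
#' @return A ggplot object.
#' @export
plot_decay_curve <- function(curve) {
  assert_df_cols(curve, c("pub_year", "fraction"))
  ggplot2::ggplot(curve, ggplot2::aes(.data$pub_year, .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Publication year", y = "URLs accessible at survey") +
    ggplot2::theme_minimal()
}

#' Authorship trend plot
#'
#' Per-year mean author counts for the series computed by
#' [authorship_trends()].
#'
#' @param trends Result of [authorship_trends()].
#' @return A ggplot object.
#' @export
plot_author_trends <- function(trends) {
  ggplot2::ggplot(trends$per_year,
                  ggplot2::aes(.data$year, .data$mean_authors,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Publication year", y = "Mean authors per paper",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname annual_gini_trend
#' @param object A `gini_trend` object.
#' @param ... Unused.
#' @method autoplot gini_trend
#' @export
autoplot.gini_trend <- function(object, ...) {
  ggplot2::ggplot(object$per_year, ggplot2::aes(.data$year, .data$gini)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Year", y = "Annual Gini coefficient") +
    ggplot2::theme_minimal()
}
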