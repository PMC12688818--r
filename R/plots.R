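#' @export
autoplot.km_curve <- function(object, ...) {
  df <- purrr::map_dfr(split(object, object$group), function(g) {
    dplyr::bind_rows(tibble::tibble(group = g$group[1], time = 0, cuminc = 0),
                     g[, c("group", "time", "cuminc")])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$cuminc,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time to onset (days)", y = "Cumulative incidence",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.weibull_tto_fit <- function(object, ...) {
  xmax <- max(object$range[2], qweibull(0.99, object$beta, object$alpha))
  grid <- tibble::tibble(
    x = seq(0.01, xmax, length.out = 400),
    density = stats::dweibull(seq(0.01, xmax, length.out = 400),
                              shape = object$beta, scale = object$alpha)
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(
      x = "Time to onset (days)", y = "Density",
      title = sprintf("Weibull fit: shape %.2f, scale %.2f (%s)",
                      object$beta, object$alpha, object$failure_type)
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of screened disproportionality signals
#'
#' Reporting odds ratios with 95% confidence intervals on a log scale,
#' significant terms highlighted.
#'
#' @param results output of [screen_signals()] / [disproportionality()].
#' @param top plot at most this many terms, ranked by ROR.
#' @return A ggplot object.
#' @export
plot_signals <- function(results, top = 30) {
  df <- results |>
    dplyr::filter(is.finite(.data$ror)) |>
    dplyr::arrange(dplyr::desc(.data$ror)) |>
    head(top) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_lo,
                                         xmax = .data$ror_hi),
                            height = 0.25) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL,
                  colour = "Significant") +
    ggplot2::theme_minimal()
}

#' @importFrom stats qweibull
NULL
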