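#' Scatter plot of a differential screen
#'
#' Parental-line SI on the x axis against resistant-line SI on the y axis,
#' one point per compound, with the hit quadrant (parental above threshold,
#' resistant below) delimited by dashed threshold lines and hits
#' highlighted.
#'
#' @param object An `mdr_hits` tibble from [call_hits()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mdr_hits
#' @export
autoplot.mdr_hits <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 50
  ggplot2::ggplot(object, ggplot2::aes(x = .data$si_parental,
                                       y = .data$si_resistant,
                                       colour = .data$is_hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(
      x = sprintf("SI %s (%%)", attr(object, "parental_line") %||% "parental"),
      y = sprintf("SI %s (%%)", attr(object, "resistant_line") %||% "resistant"),
      colour = "hit"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Observed SI points with the fitted four-parameter logistic curve on a
#' log10 concentration axis; the absolute IC50 (where the curve crosses
#' SI = 50) is marked when uncensored.
#'
#' @param object A `dr_fit` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dr_fit
#' @export
autoplot.dr_fit <- function(object, ...) {
  grid <- tibble::tibble(
    concentration = 10^seq(log10(object$c_min), log10(object$c_max),
                           length.out = 200)
  )
  grid$si <- .sigmoid(grid$concentration, object$top, object$bottom,
                      object$hill, object$midpoint %||% object$c_max)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration, y = .data$si)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "survival index (%)",
                  subtitle = paste("IC50:", object$ic50_label)) +
    ggplot2::theme_minimal()
  if (object$censor == "none") {
    p <- p + ggplot2::geom_vline(xintercept = object$ic50,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Bar chart of a compound connectivity ranking
#'
#' Mean normalized connectivity score per compound, descending — the
#' compounds whose instances most resemble the query signature at the top.
#'
#' @param object A `connectivity_ranking` from [rank_compounds()].
#' @param top_n Show at most this many compounds (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connectivity_ranking
#' @export
autoplot.connectivity_ranking <- function(object, top_n = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$mean_score,
    y = stats::reorder(.data$compound, .data$mean_score)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean normalized connectivity score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Response-rate bar chart by diagnosis
#'
#' @param object A `response_rates` object from [response_rates()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot response_rates
#' @export
autoplot.response_rates <- function(object, ...) {
  ggplot2::ggplot(object$rates, ggplot2::aes(
    x = .data$response_rate,
    y = stats::reorder(.data$diagnosis, .data$response_rate),
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = sprintf("response rate at %g uM", object$reference_concentration),
      y = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}
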