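# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a polyexponential curve
#'
#' Semilog concentration/amount vs time, the standard way disposition
#' curves are read.
#'
#' @param object a [pk_curve()].
#' @param tmax right edge of the time axis (h); default five terminal
#'   half-lives.
#' @param n number of plotted points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pk_curve
#' @export
autoplot.pk_curve <- function(object, tmax = NULL, n = 200, ...) {
  tmax <- tmax %||% 5 * log(2) / min(object$exponent)
  df <- tibble::tibble(
    time_h = seq(0, tmax, length.out = n),
    value = eval_curve(object, seq(0, tmax, length.out = n))
  )
  ylab <- if (curve_role(object) == "amount_curve") "amount (mg)" else "concentration (mg/L)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a fit over its data
#'
#' @param object a `pk_fit` from [strip_exponentials()] or [refine_fit()].
#' @param ... unused.
#' @return a ggplot with observed points and the fitted curve.
#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, ...) {
  s <- object$series
  tmax <- max(s$time_h)
  grid <- tibble::tibble(
    time_h = seq(min(s$time_h), tmax, length.out = 200)
  )
  grid$fit <- eval_curve(object$curve, grid$time_h)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_h, y = .data$conc_mg_per_L)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$fit),
      colour = "steelblue"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (mg/L)") +
    ggplot2::theme_minimal()
}

#' Plot simulated network amounts
#'
#' @param object an [fo_network()].
#' @param times sample times (h); default geometric grid over the
#'   network's rate scales.
#' @param ... unused.
#' @return a ggplot of amount vs time per species (sinks as cumulative
#'   amounts).
#' @method autoplot fo_network
#' @export
autoplot.fo_network <- function(object, times = NULL, ...) {
  rates <- object$edges$rate
  times <- times %||% exp(seq(log(0.01 / max(rates)), log(8 / min(rates)),
    length.out = 120
  ))
  df <- simulate_amounts(object, times)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_h, y = .data$amount_mg, colour = .data$species
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "amount (mg)") +
    ggplot2::theme_minimal()
}
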