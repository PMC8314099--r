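#' Plot a consumption panel
#'
#' Longitudinal profiles per country: seasonal oscillation, between-country
#' heterogeneity and gaps in reporting are all visible at a glance.
#'
#' @param object A `cp_panel` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cp_panel
#' @export
autoplot.cp_panel <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time, y = .data$value,
    group = .data$country, colour = .data$country
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = "Quarter (time index)",
      y = "Consumption (DDD per 1000 inhabitants per day)",
      colour = "Country"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted change-point model
#'
#' `type = "fit"` shows the average observed consumption per quarter (dots),
#' the population predicted curve (solid) and the de-seasonalized predicted
#' linear trend (dashed), with vertical lines at the posterior-mean
#' change-points. `type = "trace"` shows trace plots of the monitored
#' parameters by chain, the visual convergence check that accompanies split
#' R-hat.
#'
#' @param object A `cp_fit`.
#' @param type `"fit"` or `"trace"`.
#' @param pars Parameters for the trace plot; defaults to fixed effects and
#'   change-points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cp_fit
#' @export
autoplot.cp_fit <- function(object, type = c("fit", "trace"), pars = NULL,
                            ...) {
  type <- match.arg(type)
  if (type == "trace") {
    pars <- pars %||% c(
      theta_names(object$spec$k), "delta",
      if (object$spec$k > 0) paste0("cp", seq_len(object$spec$k))
    )
    pars <- intersect(pars, names(object$draws))
    long <- tidyr::pivot_longer(
      object$draws[c(".chain", ".iteration", pars)],
      cols = dplyr::all_of(pars), names_to = "term", values_to = "value"
    )
    return(
      ggplot2::ggplot(long, ggplot2::aes(
        x = .data$.iteration, y = .data$value,
        colour = factor(.data$.chain)
      )) +
        ggplot2::geom_line(alpha = 0.8) +
        ggplot2::facet_wrap(~term, scales = "free_y") +
        ggplot2::labs(x = "Retained iteration", y = NULL, colour = "Chain") +
        ggplot2::theme_minimal()
    )
  }

  obs <- dplyr::summarise(
    dplyr::group_by(object$data, .data$time),
    value = mean(.data$value), .groups = "drop"
  )
  times <- seq(min(object$data$time), max(object$data$time), by = 0.25)
  pred <- predict_population(object, times = times)
  pred_lin <- predict_population(object, times = times, seasonal = FALSE)
  cps <- if (object$spec$k > 0) {
    colMeans(object$draws[paste0("cp", seq_len(object$spec$k))])
  } else {
    numeric(0)
  }
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = pred, linewidth = 0.7) +
    ggplot2::geom_line(data = pred_lin, linetype = "dashed", linewidth = 0.7) +
    ggplot2::labs(
      x = "Quarter (time index)",
      y = "Consumption (DDD per 1000 inhabitants per day)"
    ) +
    ggplot2::theme_minimal()
  if (length(cps) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = cps, linetype = "dotted", colour = "grey40"
    )
  }
  p
}
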