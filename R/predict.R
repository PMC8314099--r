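#' Prediction curves from a fitted model
#'
#' Evaluates the mean function at the componentwise posterior means of the
#' fixed effects and change-points (the same plug-in state used for the DIC's
#' `D(theta_bar)`). With `country = NULL` all random effects are zero and
#' the curve is the population prediction; naming a country adds its
#' posterior-mean random effects. `seasonal = FALSE` drops the sine term
#' entirely, leaving the de-seasonalized piecewise-linear trend (the
#' "predicted linear" curve; the hinge terms are retained so the dashed
#' trend follows the change-points).
#'
#' @param object A `cp_fit`.
#' @param times Numeric vector of time indices; defaults to every observed
#'   quarter.
#' @param country A country id, or `NULL` for the population curve.
#' @param seasonal Include the seasonal term (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `time`, `value` and (when a country is
#'   named) `country`.
#' @export
predict.cp_fit <- function(object, times = NULL, country = NULL,
                           seasonal = TRUE, ...) {
  times <- times %||% sort(unique(object$data$time))
  state <- posterior_mean_state(object)
  if (!seasonal) {
    state$beta0S <- 0
    state$beta1S <- 0
    if (!is.null(state$ranef)) {
      state$ranef$b0S <- 0
    }
  }
  who <- if (is.null(country) || is.null(state$ranef)) NULL else country
  value <- cp_mean(object$spec, state, times, country = who)
  out <- tibble::tibble(time = as.double(times), value = value)
  if (!is.null(country)) {
    out$country <- country
    out <- out[c("country", "time", "value")]
  }
  out
}

#' @rdname predict.cp_fit
#' @param fit A `cp_fit`.
#' @export
predict_population <- function(fit, times = NULL, seasonal = TRUE) {
  predict(fit, times = times, country = NULL, seasonal = seasonal)
}

#' @rdname predict.cp_fit
#' @export
predict_country <- function(fit, country, times = NULL, seasonal = TRUE) {
  if (!country %in% fit$countries) {
    stop("unknown country: ", country, call. = FALSE)
  }
  predict(fit, times = times, country = country, seasonal = seasonal)
}
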