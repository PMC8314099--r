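#' Model specification: number of change-points and seasonal frequency
#'
#' The model combines a piecewise-linear trend with `k` common change-points
#' and a sine wave of fixed frequency `omega = 2 * pi / period`. With
#' quarterly data and an annual season, `period = 4`. The frequency is a
#' known constant, not a sampled parameter.
#'
#' @param k Integer >= 0, number of common change-points.
#' @param period Integer >= 2, time steps per seasonal cycle (default 4).
#' @return A list of class `cp_model` with elements `k`, `period`, `omega`.
#' @examples
#' cp_model(2)
#' @export
cp_model <- function(k = 0, period = 4) {
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != floor(k)) {
    stop("`k` must be a single integer >= 0.", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1 || period < 2) {
    stop("`period` must be a single number >= 2.", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), period = period, omega = 2 * pi / period),
    class = "cp_model"
  )
}

#' Positive-part (hinge) basis
#'
#' `hinge(x) = max(x, 0)`, applied elementwise. The trend term for the k-th
#' change-point is `hinge(t - cp_k)`, which makes the piecewise-linear trend
#' continuous at every change-point.
#'
#' @param x Numeric vector.
#' @return `pmax(x, 0)`.
#' @examples
#' hinge(c(-3.2, 0, 5))
#' @export
hinge <- function(x) pmax(x, 0)

ranef_cols <- function(k) {
  c("b0", "b1", "b0S", if (k > 0) paste0("bcp", seq_len(k)))
}

#' Full parameter state of the change-point model
#'
#' Bundles the fixed effects, change-point locations, country-level random
#' effects and variance components that together define one point in the
#' model's parameter space.
#'
#' @param beta0 General intercept (DDD per 1000 inhabitants per day).
#' @param beta1 General linear trend per quarter.
#' @param beta_cp Numeric vector of length `k`: differences in linear trend
#'   after versus before each change-point.
#' @param beta0S General seasonal amplitude.
#' @param beta1S General change in amplitude per quarter.
#' @param delta Phase shift of the sine wave, radians.
#' @param cps Numeric vector of length `k` of change-point locations on the
#'   time-index scale; must be strictly increasing.
#' @param ranef Tibble of country random effects with columns `country`,
#'   `b0`, `b1`, `b0S` and, for `k > 0`, `bcp1` ... `bcpk`; or `NULL` for a
#'   population-level state (all random effects zero).
#' @param sigma2 Named list of variance components: `b0`, `b1`, `b0S`, `eps`
#'   scalars and `bcp` a numeric vector of length `k`; all strictly positive.
#'
#' @return A list of class `cp_state`.
#' @export
cp_state <- function(beta0 = 0, beta1 = 0, beta_cp = numeric(0),
                     beta0S = 0, beta1S = 0, delta = 0,
                     cps = numeric(0), ranef = NULL,
                     sigma2 = list(b0 = 1, b1 = 1, bcp = rep(1, length(cps)),
                                   b0S = 1, eps = 1)) {
  k <- length(cps)
  if (length(beta_cp) != k) {
    stop("`beta_cp` and `cps` must have the same length.", call. = FALSE)
  }
  if (k > 1 && any(diff(cps) <= 0)) {
    stop("change-points must be strictly increasing.", call. = FALSE)
  }
  if (length(sigma2$bcp %||% numeric(0)) != k) {
    stop("`sigma2$bcp` must have one entry per change-point.", call. = FALSE)
  }
  if (!is.null(ranef)) {
    ranef <- tibble::as_tibble(ranef)
    missing_cols <- setdiff(c("country", ranef_cols(k)), names(ranef))
    if (length(missing_cols) > 0) {
      stop("`ranef` is missing columns: ", paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    if (anyDuplicated(ranef$country)) {
      stop("`ranef` has duplicated countries.", call. = FALSE)
    }
  }
  structure(
    list(
      beta0 = beta0, beta1 = beta1, beta_cp = as.numeric(beta_cp),
      beta0S = beta0S, beta1S = beta1S, delta = delta,
      cps = as.numeric(cps), ranef = ranef, sigma2 = sigma2
    ),
    class = "cp_state"
  )
}

state_k <- function(state) length(state$cps)

ranef_row <- function(state, country) {
  if (is.null(state$ranef)) {
    k <- state_k(state)
    return(stats::setNames(rep(0, 3 + k), ranef_cols(k)))
  }
  i <- match(country, state$ranef$country)
  if (is.na(i)) {
    stop("unknown country: ", country, call. = FALSE)
  }
  unlist(state$ranef[i, ranef_cols(state_k(state))])
}

#' Evaluate the model mean function
#'
#' The mean consumption for a country at time `t` is
#' \deqn{(\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) t +
#'   \sum_k (\beta_{k+1} + b_{(k+1)i}) (t - CP_k)_+ +
#'   (\beta_0^S + b_{0i}^S + \beta_1^S t) \sin(\omega t + \delta)}
#' With `k = 0` the hinge sum vanishes and the model reduces to a linear
#' trend plus seasonality; `country = NULL` evaluates the population curve
#' (all random effects zero).
#'
#' @param spec A [cp_model()].
#' @param state A [cp_state()] with the same number of change-points.
#' @param t Numeric vector of time indices (>= 1).
#' @param country A single country id present in `state$ranef`, or `NULL`.
#' @return Numeric vector of means, one per element of `t`.
#' @export
cp_mean <- function(spec, state, t, country = NULL) {
  if (state_k(state) != spec$k) {
    stop("state and spec disagree on the number of change-points.",
      call. = FALSE
    )
  }
  b <- if (is.null(country)) {
    stats::setNames(rep(0, 3 + spec$k), ranef_cols(spec$k))
  } else {
    ranef_row(state, country)
  }
  mu <- (state$beta0 + b[["b0"]]) + (state$beta1 + b[["b1"]]) * t
  for (j in seq_len(spec$k)) {
    mu <- mu + (state$beta_cp[j] + b[[paste0("bcp", j)]]) *
      hinge(t - state$cps[j])
  }
  mu + (state$beta0S + b[["b0S"]] + state$beta1S * t) *
    sin(spec$omega * t + state$delta)
}

#' Conditional Gaussian log-likelihood of a panel
#'
#' Sum over observed records of the normal log-density of `value` given the
#' model mean and residual variance `sigma2$eps`, conditional on the random
#' effects. Absent quarters contribute nothing, so unbalanced panels need no
#' special handling.
#'
#' @param data A `cp_panel` tibble (see [as_panel()]).
#' @param spec A [cp_model()].
#' @param state A [cp_state()]; every country in `data` must appear in
#'   `state$ranef` (or `ranef` must be `NULL` for an all-zero state).
#' @return The log-likelihood (a single number).
#' @export
cp_loglik <- function(data, spec, state) {
  if (!is.finite(state$sigma2$eps) || state$sigma2$eps <= 0) {
    stop("`sigma2$eps` must be > 0.", call. = FALSE)
  }
  if (nrow(data) == 0) {
    return(0)
  }
  mu <- numeric(nrow(data))
  for (cc in unique(data$country)) {
    sel <- data$country == cc
    who <- if (is.null(state$ranef)) NULL else cc
    mu[sel] <- cp_mean(spec, state, data$time[sel], country = who)
  }
  sum(stats::dnorm(data$value, mu, sqrt(state$sigma2$eps), log = TRUE))
}

#' Deviance of a panel under a parameter state
#'
#' `-2` times [cp_loglik()]; the conditional (given random effects) deviance
#' used by the DIC machinery.
#'
#' @inheritParams cp_loglik
#' @return The deviance (a single number).
#' @export
cp_deviance <- function(data, spec, state) {
  -2 * cp_loglik(data, spec, state)
}
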