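#' Prior configuration
#'
#' The default prior stack is deliberately uninformative: every regression
#' coefficient (including the phase shift) gets a Normal(0, 1000) prior
#' (variance 1000, i.e. precision 0.001), the first change-point is Uniform
#' over the whole observed time range, each further change-point is Uniform
#' between its predecessor and the end of the range (which enforces the
#' ordering and prevents label switching), and every variance component has
#' an inverse-gamma IGamma(0.001, 0.001) prior in the shape--rate
#' parameterisation (1/x is Gamma with mean shape/rate).
#'
#' @param coef_mean Prior mean of the regression coefficients (default 0).
#' @param coef_variance Prior variance of the regression coefficients
#'   (default 1000).
#' @param cp_lower Lower end of the first change-point's support (default 1).
#' @param cp_upper Upper end of every change-point's support; `NULL` (the
#'   default) means "the largest observed time index", resolved when a panel
#'   is available (84 for a 1997--2017 quarterly study).
#' @param igamma_shape,igamma_rate Inverse-gamma hyperparameters for all
#'   variance components (default 0.001 each).
#'
#' @return A list of class `cp_priors`.
#' @export
cp_priors <- function(coef_mean = 0, coef_variance = 1000,
                      cp_lower = 1, cp_upper = NULL,
                      igamma_shape = 0.001, igamma_rate = 0.001) {
  if (coef_variance <= 0 || igamma_shape <= 0 || igamma_rate <= 0) {
    stop("prior variance and inverse-gamma hyperparameters must be > 0.",
      call. = FALSE
    )
  }
  if (!is.null(cp_upper) && cp_lower >= cp_upper) {
    stop("`cp_lower` must be below `cp_upper`.", call. = FALSE)
  }
  structure(
    list(
      coef_mean = coef_mean, coef_variance = coef_variance,
      cp_lower = cp_lower, cp_upper = cp_upper,
      igamma_shape = igamma_shape, igamma_rate = igamma_rate
    ),
    class = "cp_priors"
  )
}

resolve_priors <- function(priors, t_max) {
  if (is.null(priors$cp_upper)) {
    priors$cp_upper <- t_max
  }
  if (priors$cp_lower >= priors$cp_upper) {
    stop("change-point support is empty: cp_lower >= cp_upper.", call. = FALSE)
  }
  priors
}

#' Log prior density of a parameter state
#'
#' Sums the log-densities of all components under the prior stack of
#' [cp_priors()]. States outside the support (change-points out of order or
#' outside `[cp_lower, cp_upper]`, non-positive variances) get `-Inf` rather
#' than an error, so the value can be used directly in an MCMC acceptance
#' ratio.
#'
#' @param state A [cp_state()].
#' @param spec A [cp_model()] consistent with `state`.
#' @param priors A [cp_priors()] with a resolved (non-`NULL`) `cp_upper`.
#' @return A single number, possibly `-Inf`.
#' @export
log_prior <- function(state, spec, priors = cp_priors(cp_upper = 84)) {
  if (is.null(priors$cp_upper)) {
    stop("`cp_upper` is unresolved; pass cp_priors(cp_upper = ...) or fit a panel.",
      call. = FALSE
    )
  }
  k <- spec$k
  s2 <- state$sigma2
  variances <- c(s2$b0, s2$b1, s2$bcp, s2$b0S, s2$eps)
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    return(-Inf)
  }

  # ordered-uniform change-point support
  if (k > 0) {
    bounds <- c(priors$cp_lower, state$cps)
    if (any(diff(bounds) <= 0) || any(state$cps >= priors$cp_upper)) {
      return(-Inf)
    }
  }

  lp <- sum(stats::dnorm(
    c(state$beta0, state$beta1, state$beta_cp, state$beta0S, state$beta1S,
      state$delta),
    priors$coef_mean, sqrt(priors$coef_variance),
    log = TRUE
  ))
  if (k > 0) {
    lower <- c(priors$cp_lower, state$cps[-k])
    lp <- lp + sum(stats::dunif(state$cps, lower, priors$cp_upper, log = TRUE))
  }
  lp <- lp + sum(dinvgamma_log(variances, priors$igamma_shape, priors$igamma_rate))

  if (!is.null(state$ranef)) {
    re <- state$ranef
    lp <- lp + sum(stats::dnorm(re$b0, 0, sqrt(s2$b0), log = TRUE)) +
      sum(stats::dnorm(re$b1, 0, sqrt(s2$b1), log = TRUE)) +
      sum(stats::dnorm(re$b0S, 0, sqrt(s2$b0S), log = TRUE))
    for (j in seq_len(k)) {
      lp <- lp + sum(stats::dnorm(re[[paste0("bcp", j)]], 0, sqrt(s2$bcp[j]),
        log = TRUE
      ))
    }
  }
  lp
}

#' Draw a parameter state from the prior
#'
#' Draws variance components from the inverse-gamma prior, random effects
#' from their zero-mean normals given those variances, coefficients from
#' Normal(`coef_mean`, `coef_variance`), the first change-point from
#' Uniform(`cp_lower`, `cp_upper`) and each subsequent change-point from
#' Uniform(previous, `cp_upper`). The returned state always has a finite
#' [log_prior()].
#'
#' @param spec A [cp_model()].
#' @param n_countries Integer >= 0; countries are labelled `"C1"`, `"C2"`, ...
#'   With 0 countries the state carries no random effects.
#' @param priors A [cp_priors()] with resolved `cp_upper`.
#' @return A [cp_state()].
#' @export
sample_prior <- function(spec, n_countries = 1,
                         priors = cp_priors(cp_upper = 84)) {
  if (is.null(priors$cp_upper)) {
    stop("`cp_upper` is unresolved; pass cp_priors(cp_upper = ...).",
      call. = FALSE
    )
  }
  k <- spec$k
  a <- priors$igamma_shape
  b <- priors$igamma_rate
  sigma2 <- list(
    b0 = rinvgamma(1, a, b), b1 = rinvgamma(1, a, b),
    bcp = rinvgamma(k, a, b), b0S = rinvgamma(1, a, b),
    eps = rinvgamma(1, a, b)
  )
  ranef <- NULL
  if (n_countries > 0) {
    ranef <- tibble::tibble(
      country = paste0("C", seq_len(n_countries)),
      b0 = stats::rnorm(n_countries, 0, sqrt(sigma2$b0)),
      b1 = stats::rnorm(n_countries, 0, sqrt(sigma2$b1)),
      b0S = stats::rnorm(n_countries, 0, sqrt(sigma2$b0S))
    )
    for (j in seq_len(k)) {
      ranef[[paste0("bcp", j)]] <-
        stats::rnorm(n_countries, 0, sqrt(sigma2$bcp[j]))
    }
  }
  coefs <- stats::rnorm(4 + k, priors$coef_mean, sqrt(priors$coef_variance))
  cps <- numeric(k)
  lower <- priors$cp_lower
  for (j in seq_len(k)) {
    cps[j] <- stats::runif(1, lower, priors$cp_upper)
    lower <- cps[j]
  }
  cp_state(
    beta0 = coefs[1], beta1 = coefs[2],
    beta_cp = if (k > 0) coefs[2 + seq_len(k)] else numeric(0),
    beta0S = coefs[3 + k], beta1S = coefs[4 + k],
    delta = stats::rnorm(1, priors$coef_mean, sqrt(priors$coef_variance)),
    cps = cps, ranef = ranef, sigma2 = sigma2
  )
}
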