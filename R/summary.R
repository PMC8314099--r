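#' Tidy posterior summary of a fitted change-point model
#'
#' One row per monitored parameter, chains pooled: posterior mean, posterior
#' standard deviation (reported as `std.error`, the Bayesian analogue of the
#' frequentist standard error in summary tables), equal-tailed 95% credible
#' interval, and convergence diagnostics.
#'
#' @param x A `cp_fit`.
#' @param conf.level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess`.
#' @method tidy cp_fit
#' @export
tidy.cp_fit <- function(x, conf.level = 0.95, ...) {
  terms <- monitored_terms(x)
  alpha <- (1 - conf.level) / 2
  base <- purrr::map_dfr(terms, function(term) {
    v <- x$draws[[term]]
    tibble::tibble(
      term = term,
      estimate = mean(v),
      std.error = stats::sd(v),
      conf.low = unname(stats::quantile(v, alpha)),
      conf.high = unname(stats::quantile(v, 1 - alpha))
    )
  })
  if (length(unique(x$draws$.chain)) >= 2) {
    conv <- assess_convergence(x)
    base <- dplyr::left_join(base, conv, by = "term")
  } else {
    base$rhat <- NA_real_
    base$ess <- NA_real_
  }
  base
}

#' One-row model summary
#'
#' @param x A `cp_fit`.
#' @param ... Unused.
#' @return A one-row tibble: the [compute_dic()] fields plus draw counts.
#' @method glance cp_fit
#' @export
glance.cp_fit <- function(x, ...) {
  dic <- compute_dic(x)
  dic$n_obs <- nrow(x$data)
  dic$n_countries <- length(x$countries)
  dic$n_draws <- nrow(x$draws)
  dic
}

#' Posterior summary table with calendar change-point locations
#'
#' The standard reporting layout for this model family: posterior means and
#' standard deviations for the fixed effects, change-points and variance
#' components, with each change-point's posterior-mean location also
#' rendered as a calendar quarter (floor convention: index 44.529 lies in
#' quarter 44, i.e. 2007 Q4 with a 1997 Q1 origin).
#'
#' @param fit A `cp_fit`.
#' @param origin A [calendar_quarter()]; defaults to the panel's origin.
#' @return A tibble `term`, `estimate`, `std.error`, `calendar` (`NA` except
#'   for change-point rows).
#' @export
summarize_posterior <- function(fit, origin = NULL) {
  origin <- origin %||% panel_origin(fit$data)
  out <- tidy(fit)[c("term", "estimate", "std.error")]
  out$calendar <- NA_character_
  cp_rows <- grepl("^cp[0-9]+$", out$term)
  if (any(cp_rows)) {
    out$calendar[cp_rows] <- format_quarter(out$estimate[cp_rows], origin)
  }
  out
}
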