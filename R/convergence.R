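# split-chain potential scale reduction for one parameter
# x: matrix, iterations x chains
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) {
    return(NA_real_)
  }
  half <- n %/% 2
  splits <- cbind(
    x[seq_len(half), , drop = FALSE],
    x[(n - half + 1):n, , drop = FALSE]
  )
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (!is.finite(w) || w == 0) {
    # constant sequences: identical chains are trivially converged
    return(if (stats::var(means) == 0 || !is.finite(b)) 1 else Inf)
  }
  sqrt(((half - 1) / half * w + b / half) / w)
}

# effective sample size pooled over chains (initial monotone-ish truncation)
ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) {
    return(NA_real_)
  }
  w <- mean(apply(x, 2, stats::var))
  if (!is.finite(w) || w == 0) {
    return(n * m)
  }
  max_lag <- min(n - 2, 500)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
      demean = TRUE
    )$acf[-1, 1, 1]
  }, numeric(max_lag)))
  # truncate at the first lag pair with non-positive sum (Geyer-style)
  s <- 0
  lag <- 1
  while (lag + 1 <= max_lag) {
    pair <- rho[lag] + rho[lag + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    lag <- lag + 2
  }
  max(n * m / (1 + 2 * s), 1)
}

#' Assess MCMC convergence of a fitted model
#'
#' Convergence is operationalized as split-chain potential scale reduction
#' (split R-hat): each chain is split in half, and the between- to
#' within-sequence variance ratio is computed per parameter. The fit is
#' declared converged when every monitored parameter (fixed effects, phase
#' shift, change-points and variance components) has R-hat at or below the
#' threshold. Effective sample sizes are reported alongside. Parameters held
#' fixed during sampling are constant and trivially converged.
#'
#' @param fit A `cp_fit` object with at least two chains.
#' @param rhat_threshold Threshold for declaring convergence; defaults to
#'   the value in the fit's control (1.1).
#'
#' @return A tibble with columns `term`, `rhat`, `ess`, plus an attribute
#'   `converged` (also available via [glance()]).
#' @export
assess_convergence <- function(fit, rhat_threshold = NULL) {
  n_chains <- length(unique(fit$draws$.chain))
  if (n_chains < 2) {
    stop("convergence diagnosis needs at least 2 chains.", call. = FALSE)
  }
  rhat_threshold <- rhat_threshold %||% fit$control$rhat_threshold
  terms <- monitored_terms(fit)
  per_chain <- split(fit$draws, fit$draws$.chain)
  n_iter <- min(vapply(per_chain, nrow, integer(1)))
  res <- purrr::map_dfr(terms, function(term) {
    x <- matrix(
      unlist(lapply(per_chain, function(d) d[[term]][seq_len(n_iter)])),
      nrow = n_iter
    )
    tibble::tibble(
      term = term,
      rhat = split_rhat(x),
      ess = ess_basic(x)
    )
  })
  converged <- all(is.na(res$rhat) | res$rhat <= rhat_threshold)
  attr(res, "converged") <- converged
  attr(res, "rhat_threshold") <- rhat_threshold
  res
}

monitored_terms <- function(fit) {
  k <- fit$spec$k
  terms <- scalar_param_names(k)
  fixed <- names(fit$control$fix)
  if ("cps" %in% fixed && k > 0) {
    fixed <- c(fixed, paste0("cp", seq_len(k)))
  }
  setdiff(terms, fixed)
}

#' Is a fitted model converged?
#'
#' @param fit A `cp_fit`.
#' @param ... Passed to [assess_convergence()].
#' @return `TRUE`/`FALSE`.
#' @export
is_converged <- function(fit, ...) {
  attr(assess_convergence(fit, ...), "converged")
}
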