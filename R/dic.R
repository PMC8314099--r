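# reconstruct a cp_state from the componentwise posterior means of the draws
posterior_mean_state <- function(fit) {
  state_from_values(fit, function(nm) mean(fit$draws[[nm]]))
}

# reconstruct the full cp_state held at one retained draw
state_from_draw <- function(fit, row) {
  state_from_values(fit, function(nm) fit$draws[[nm]][row])
}

state_from_values <- function(fit, m) {
  k <- fit$spec$k
  ranef <- NULL
  if (fit$use_ranef) {
    col <- function(prefix) {
      unname(vapply(fit$countries,
        function(cc) m(paste0(prefix, "[", cc, "]")), 0
      ))
    }
    ranef <- tibble::tibble(
      country = fit$countries,
      b0 = col("b0"), b1 = col("b1"), b0S = col("b0S")
    )
    for (j in seq_len(k)) {
      ranef[[paste0("bcp", j)]] <- col(paste0("bcp", j))
    }
  }
  cp_state(
    beta0 = m("beta0"), beta1 = m("beta1"),
    beta_cp = if (k > 0) vapply(paste0("beta_cp", seq_len(k)), m, 0) else numeric(0),
    beta0S = m("beta0S"), beta1S = m("beta1S"), delta = m("delta"),
    cps = if (k > 0) vapply(paste0("cp", seq_len(k)), m, 0) else numeric(0),
    ranef = ranef,
    sigma2 = list(
      b0 = m("sigma2_b0"), b1 = m("sigma2_b1"),
      bcp = if (k > 0) vapply(paste0("sigma2_bcp", seq_len(k)), m, 0) else numeric(0),
      b0S = m("sigma2_b0S"), eps = m("sigma2_eps")
    )
  )
}

#' Deviance Information Criterion of a fitted model
#'
#' Computes both DIC variants from the retained draws: the pD form, where
#' the effective number of parameters is `pD = Dbar - D(theta_bar)` with
#' `D(theta_bar)` the conditional deviance at the componentwise posterior
#' mean of all sampled quantities (random effects included), and the pV
#' form, where `pV = Var(deviance) / 2`. `pD` can be negative under strong
#' non-normality of the posterior; `pV` is non-negative by construction and
#' serves as the fallback. Smaller DIC means a better fitting model.
#'
#' @param fit A `cp_fit` with at least two retained draws.
#'
#' @return A one-row tibble: `k`, `dbar`, `dhat`, `pd`, `pv`, `dic_pd`
#'   (= `dbar + pd` = `2 dbar - dhat`), `dic_pv` (= `dbar + pv`) and
#'   `converged`.
#' @export
compute_dic <- function(fit) {
  dev <- fit$draws$deviance
  if (length(dev) < 2) {
    stop("DIC needs at least 2 retained draws.", call. = FALSE)
  }
  dbar <- mean(dev)
  dhat <- cp_deviance(fit$data, fit$spec, posterior_mean_state(fit))
  pd <- dbar - dhat
  pv <- stats::var(dev) / 2
  converged <- if (length(unique(fit$draws$.chain)) >= 2) {
    is_converged(fit)
  } else {
    NA
  }
  tibble::tibble(
    k = fit$spec$k, dbar = dbar, dhat = dhat, pd = pd, pv = pv,
    dic_pd = dbar + pd, dic_pv = dbar + pv, converged = converged
  )
}

#' Compare models with 0 to `k_max` change-points
#'
#' Fits the model for each number of change-points in turn and tabulates
#' both DIC variants with a convergence flag. The selected model is the one
#' with the smallest DIC among converged fits (non-converged fits — the
#' typical symptom of asking for more change-points than the data support —
#' are reported but excluded from selection).
#'
#' @param data A `cp_panel` tibble.
#' @param k_max Largest number of change-points to try (>= 0).
#' @param priors A [cp_priors()].
#' @param control A [cp_control()]; the same protocol is used for every fit.
#' @param criterion `"dic_pd"` (default) or `"dic_pv"`.
#' @param period Quarters per seasonal cycle.
#'
#' @return A tibble with one row per candidate `k`: the [compute_dic()]
#'   columns plus `selected`. The fitted models are attached as attribute
#'   `fits`.
#' @export
cp_compare <- function(data, k_max, priors = cp_priors(),
                       control = cp_control(), criterion = c("dic_pd", "dic_pv"),
                       period = 4) {
  criterion <- match.arg(criterion)
  fits <- lapply(0:k_max, function(k) {
    cp_fit(data, k = k, priors = priors, control = control, period = period)
  })
  tab <- dplyr::bind_rows(lapply(fits, compute_dic))
  eligible <- which(tab$converged %in% TRUE)
  if (length(eligible) == 0) {
    eligible <- seq_len(nrow(tab)) # nothing converged: fall back to all
  }
  best <- eligible[which.min(tab[[criterion]][eligible])]
  tab$selected <- seq_len(nrow(tab)) == best
  attr(tab, "fits") <- fits
  tab
}
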