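#' Sampler configuration
#'
#' Defaults follow the recommended fitting protocol for this model family:
#' two chains of 110 000 iterations, the first 10 000 discarded as burn-in,
#' and thinning to every 5th draw to blunt the autocorrelation of the
#' change-point and phase parameters. Tests and quick exploration use much
#' smaller counts.
#'
#' @param chains Number of chains (>= 2 for convergence diagnosis).
#' @param iterations Iterations per chain.
#' @param burnin Burn-in iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; the same seed reproduces the draws exactly.
#' @param adapt Adapt Metropolis proposal scales during burn-in towards a
#'   20--50% acceptance rate, then freeze them (adapting after burn-in would
#'   break detailed balance).
#' @param proposal_scale_delta Initial random-walk scale for the phase shift.
#' @param proposal_scale_cp Initial random-walk scale (quarters) for each
#'   change-point.
#' @param rhat_threshold Convergence is declared when every monitored
#'   parameter has split R-hat at or below this value (default 1.1).
#' @param fix Named list of parameters to hold fixed rather than sample;
#'   names among `beta0`, `beta1`, `beta_cp1` ..., `beta0S`, `beta1S`,
#'   `delta`, `sigma2_eps`, `cps`. Used for oracle checks and restricted
#'   fits.
#' @param random_effects Set `FALSE` to drop all country random effects
#'   (e.g. for a single-country analysis).
#'
#' @return A list of class `cp_control`.
#' @export
cp_control <- function(chains = 2, iterations = 110000, burnin = 10000,
                       thin = 5, seed = 1, adapt = TRUE,
                       proposal_scale_delta = 0.1, proposal_scale_cp = 2,
                       rhat_threshold = 1.1, fix = list(),
                       random_effects = TRUE) {
  if (burnin >= iterations) {
    stop("`burnin` must be smaller than `iterations`.", call. = FALSE)
  }
  if (thin < 1) {
    stop("`thin` must be >= 1.", call. = FALSE)
  }
  structure(
    list(
      chains = as.integer(chains), iterations = as.integer(iterations),
      burnin = as.integer(burnin), thin = as.integer(thin),
      seed = as.integer(seed), adapt = isTRUE(adapt),
      proposal_scale_delta = proposal_scale_delta,
      proposal_scale_cp = proposal_scale_cp,
      rhat_threshold = rhat_threshold,
      fix = fix, random_effects = isTRUE(random_effects)
    ),
    class = "cp_control"
  )
}

#' Fit the Bayesian change-point model to a panel
#'
#' Draws from the posterior of all model parameters by
#' Metropolis-within-Gibbs. The linear structure is sampled exactly from its
#' Gaussian full conditionals (joint draw for the fixed-effect block, per
#' country for the random effects), variance components from their conjugate
#' inverse-gamma full conditionals, and the phase shift and each
#' change-point by random-walk Metropolis. Change-point proposals outside
#' the ordered support, or leaving fewer than two observed time points on
#' either side, are rejected. The conditional deviance is recorded at every
#' retained draw.
#'
#' @param data A `cp_panel` tibble (see [as_panel()]); a zero-row panel is
#'   allowed, in which case the posterior is the prior.
#' @param k Number of common change-points (>= 0).
#' @param priors A [cp_priors()]. An unresolved `cp_upper` defaults to the
#'   largest observed time index.
#' @param control A [cp_control()].
#' @param period Quarters per seasonal cycle (default 4).
#'
#' @return An object of class `cp_fit`: a list with `draws` (tibble, one row
#'   per retained draw, columns `.chain`, `.iteration`, every scalar
#'   parameter including per-country random effects, and `deviance`),
#'   `spec`, `priors`, `control`, `data`, `accept_rates`.
#' @examples
#' \donttest{
#' panel <- simulate_panel(n_countries = 4, t_max = 40, seed = 1)
#' fit <- cp_fit(panel, k = 2,
#'               control = cp_control(iterations = 2000, burnin = 500,
#'                                    thin = 2, seed = 1))
#' glance(fit)
#' }
#' @export
cp_fit <- function(data, k = 0, priors = cp_priors(),
                   control = cp_control(), period = 4) {
  spec <- cp_model(k = k, period = period)
  if (!inherits(data, "cp_panel")) {
    data <- as_panel(data)
  }
  n <- nrow(data)
  t_max <- if (n > 0) max(data$time) else NULL
  if (is.null(priors$cp_upper) && is.null(t_max)) {
    stop("empty panel with unresolved `cp_upper`: pass cp_priors(cp_upper = ...).",
      call. = FALSE
    )
  }
  priors <- resolve_priors(priors, t_max %||% 84)

  countries <- if (n > 0) sort(unique(data$country)) else character(0)
  use_ranef <- control$random_effects && length(countries) > 0

  ut <- if (n > 0) sort(unique(data$time)) else numeric(0)
  if (k > 0 && n > 0 && length(ut) < k + 4) {
    stop("too few distinct time points to support ", k,
      " change-points; reduce the number of change-points.",
      call. = FALSE
    )
  }

  set.seed(control$seed)
  chains <- lapply(seq_len(control$chains), function(chain) {
    run_chain(data, spec, priors, control, countries, use_ranef, chain)
  })

  draws <- dplyr::bind_rows(lapply(seq_along(chains), function(i) {
    d <- tibble::as_tibble(chains[[i]]$draws)
    d$.chain <- i
    d$.iteration <- seq_len(nrow(d))
    dplyr::relocate(d, ".chain", ".iteration")
  }))
  accept <- do.call(rbind, lapply(chains, function(ch) ch$accept))

  structure(
    list(
      draws = draws, spec = spec, priors = priors, control = control,
      data = data, countries = countries, use_ranef = use_ranef,
      accept_rates = accept
    ),
    class = "cp_fit"
  )
}

theta_names <- function(k) {
  c("beta0", "beta1", if (k > 0) paste0("beta_cp", seq_len(k)),
    "beta0S", "beta1S")
}

scalar_param_names <- function(k) {
  c(theta_names(k), "delta", if (k > 0) paste0("cp", seq_len(k)),
    "sigma2_b0", "sigma2_b1",
    if (k > 0) paste0("sigma2_bcp", seq_len(k)),
    "sigma2_b0S", "sigma2_eps")
}

# one MCMC chain; pure R, vectorised over observations
run_chain <- function(data, spec, priors, control, countries, use_ranef,
                      chain) {
  k <- spec$k
  omega <- spec$omega
  n <- nrow(data)
  y <- data$value
  tt <- as.double(data$time)
  ci <- match(data$country, countries)
  n_cty <- length(countries)
  idx <- if (use_ranef) split(seq_len(n), ci) else list()
  ut <- sort(unique(tt))

  v0 <- priors$coef_variance
  m0 <- priors$coef_mean
  ig_a <- priors$igamma_shape
  ig_b <- priors$igamma_rate
  cp_lo <- priors$cp_lower
  cp_hi <- priors$cp_upper

  fix <- control$fix
  tn <- theta_names(k)
  p <- length(tn)
  free <- !(tn %in% names(fix))
  fix_delta <- "delta" %in% names(fix)
  fix_s2e <- "sigma2_eps" %in% names(fix)
  fix_cps <- "cps" %in% names(fix)

  # --- initial state: deterministic defaults + chain jitter ---------------
  theta <- stats::setNames(rep(0, p), tn)
  for (nm in intersect(tn, names(fix))) theta[nm] <- fix[[nm]]
  theta[free] <- theta[free] + stats::rnorm(sum(free), 0, 0.1)
  delta <- if (fix_delta) fix$delta else stats::rnorm(1, 0, 0.05)
  if (fix_cps) {
    cps <- as.double(fix$cps)
    if (length(cps) != k) stop("`fix$cps` must have length k.", call. = FALSE)
  } else if (k > 0) {
    cps <- cp_lo + (cp_hi - cp_lo) * seq_len(k) / (k + 1)
    cps <- sort(cps + stats::rnorm(k, 0, 0.5))
    cps <- pmin(pmax(cps, cp_lo + 1e-6), cp_hi - 1e-6)
    if (any(diff(cps) <= 0)) cps <- sort(cps)
  } else {
    cps <- numeric(0)
  }
  if (k > 0 && n > 0) {
    ok <- vapply(cps, function(cc) {
      sum(ut < cc) >= 2 && sum(ut > cc) >= 2
    }, logical(1))
    if (!all(ok)) {
      stop("initial change-point support collapses; reduce the number of ",
        "change-points or widen the panel.",
        call. = FALSE
      )
    }
  }
  sigma2 <- list(b0 = 1, b1 = 1, bcp = rep(1, k), b0S = 1,
                 eps = if (fix_s2e) fix$sigma2_eps else 1)
  b <- if (use_ranef) matrix(0, n_cty, 3 + k) else NULL

  s <- sin(omega * tt + delta)
  H <- if (k > 0) {
    vapply(cps, function(cc) hinge(tt - cc), numeric(n))
  } else {
    matrix(0, n, 0)
  }
  if (n == 0) H <- matrix(0, 0, k)

  mean_of <- function(theta, b, H, s) {
    mu <- theta[1] + theta[2] * tt
    for (j in seq_len(k)) mu <- mu + theta[2 + j] * H[, j]
    mu <- mu + (theta[3 + k] + theta[4 + k] * tt) * s
    if (!is.null(b)) {
      mu <- mu + b[ci, 1] + b[ci, 2] * tt
      for (j in seq_len(k)) mu <- mu + b[ci, 2 + j] * H[, j]
      mu <- mu + b[ci, 3 + k] * s
    }
    mu
  }

  n_keep <- (control$iterations - control$burnin) %/% control$thin
  # as.vector(t(b)) stacks per-country blocks (b0, b1, bcp..., b0S)
  b_names <- if (use_ranef) {
    as.vector(outer(c("b0", "b1", if (k > 0) paste0("bcp", seq_len(k)),
                      "b0S"),
                    countries, function(a, cc) paste0(a, "[", cc, "]")))
  } else {
    character(0)
  }
  col_names <- c(scalar_param_names(k), b_names, "deviance")
  out <- matrix(NA_real_, n_keep, length(col_names),
    dimnames = list(NULL, col_names)
  )

  # Metropolis bookkeeping
  sd_delta <- control$proposal_scale_delta
  sd_cp <- rep(control$proposal_scale_cp, k)
  acc <- stats::setNames(rep(0, 1 + k), c("delta", if (k > 0) paste0("cp", seq_len(k))))
  try_n <- acc
  batch_acc <- acc
  batch_n <- acc

  mu <- mean_of(theta, b, H, s)
  ssr <- if (n > 0) sum((y - mu)^2) else 0
  row <- 0L

  for (iter in seq_len(control$iterations)) {
    in_burnin <- iter <= control$burnin

    # --- fixed-effect block -----------------------------------------------
    # Collapsed Gibbs draw: random effects are integrated out of the
    # likelihood (Woodbury, per country), so theta and b are updated as one
    # joint block. This removes the near-nonidentified coupling between the
    # population intercept and the mean of the random intercepts, which
    # otherwise mixes at a crawl under the flat coefficient prior.
    if (any(free)) {
      s2e <- sigma2$eps
      A <- diag(1 / v0, p)
      rhs <- rep(m0 / v0, p)
      if (n > 0) X <- cbind(1, tt, H, s, tt * s)
      if (n > 0 && use_ranef) {
        d_inv <- 1 / c(sigma2$b0, sigma2$b1, sigma2$bcp, sigma2$b0S)
        for (i in seq_len(n_cty)) {
          ii <- idx[[as.character(i)]]
          Xi <- X[ii, , drop = FALSE]
          Zi <- Xi[, seq_len(p - 1), drop = FALSE]
          Mi <- chol2inv(chol(diag(d_inv, p - 1) + crossprod(Zi) / s2e))
          Ui <- crossprod(Zi, Xi)
          wi <- crossprod(Zi, y[ii])[, 1]
          A <- A + (crossprod(Xi) - crossprod(Ui, Mi %*% Ui) / s2e) / s2e
          rhs <- rhs +
            (crossprod(Xi, y[ii])[, 1] - crossprod(Ui, Mi %*% wi)[, 1] / s2e) / s2e
        }
      } else if (n > 0) {
        A <- A + crossprod(X) / s2e
        rhs <- rhs + crossprod(X, y)[, 1] / s2e
      }
      if (all(free)) {
        ch <- chol(A)
        mean_f <- backsolve(ch, forwardsolve(t(ch), rhs))
        theta <- stats::setNames(
          mean_f + backsolve(ch, stats::rnorm(p)), tn
        )
      } else {
        # condition the joint Gaussian on the coordinates held fixed
        A_ff <- A[free, free, drop = FALSE]
        rhs_f <- rhs[free] -
          A[free, !free, drop = FALSE] %*% theta[!free]
        ch <- chol(A_ff)
        mean_f <- backsolve(ch, forwardsolve(t(ch), rhs_f))
        theta[free] <- mean_f + backsolve(ch, stats::rnorm(sum(free)))
      }
    }

    # --- random effects: per-country Gaussian full conditionals -----------
    if (use_ranef) {
      X <- cbind(1, tt, H, s, tt * s)
      xb <- X %*% theta
      Z <- X[, seq_len(p - 1), drop = FALSE]
      d_inv <- 1 / c(sigma2$b0, sigma2$b1, sigma2$bcp, sigma2$b0S)
      for (i in seq_len(n_cty)) {
        ii <- idx[[as.character(i)]]
        Zi <- Z[ii, , drop = FALSE]
        A <- crossprod(Zi) / sigma2$eps + diag(d_inv, p - 1)
        rhs <- crossprod(Zi, y[ii] - xb[ii])[, 1] / sigma2$eps
        ch <- chol(A)
        mean_i <- backsolve(ch, forwardsolve(t(ch), rhs))
        b[i, ] <- mean_i + backsolve(ch, stats::rnorm(p - 1))
      }
    }

    mu <- mean_of(theta, b, H, s)
    ssr <- if (n > 0) sum((y - mu)^2) else 0

    # --- variance components: conjugate inverse-gamma ---------------------
    if (use_ranef) {
      sigma2$b0 <- rinvgamma(1, ig_a + n_cty / 2, ig_b + sum(b[, 1]^2) / 2)
      sigma2$b1 <- rinvgamma(1, ig_a + n_cty / 2, ig_b + sum(b[, 2]^2) / 2)
      for (j in seq_len(k)) {
        sigma2$bcp[j] <-
          rinvgamma(1, ig_a + n_cty / 2, ig_b + sum(b[, 2 + j]^2) / 2)
      }
      sigma2$b0S <- rinvgamma(1, ig_a + n_cty / 2, ig_b + sum(b[, 3 + k]^2) / 2)
    } else {
      sigma2$b0 <- rinvgamma(1, ig_a, ig_b)
      sigma2$b1 <- rinvgamma(1, ig_a, ig_b)
      if (k > 0) sigma2$bcp <- rinvgamma(k, ig_a, ig_b)
      sigma2$b0S <- rinvgamma(1, ig_a, ig_b)
    }
    if (!fix_s2e) {
      sigma2$eps <- rinvgamma(1, ig_a + n / 2, ig_b + ssr / 2)
    }

    # --- phase shift: random-walk Metropolis ------------------------------
    if (!fix_delta) {
      delta_star <- delta + sd_delta * stats::rnorm(1)
      s_star <- sin(omega * tt + delta_star)
      mu_star <- mean_of(theta, b, H, s_star)
      ssr_star <- if (n > 0) sum((y - mu_star)^2) else 0
      log_acc <- -0.5 * (ssr_star - ssr) / sigma2$eps +
        stats::dnorm(delta_star, m0, sqrt(v0), log = TRUE) -
        stats::dnorm(delta, m0, sqrt(v0), log = TRUE)
      try_n["delta"] <- try_n["delta"] + !in_burnin
      batch_n["delta"] <- batch_n["delta"] + 1
      if (log(stats::runif(1)) < log_acc) {
        delta <- delta_star
        s <- s_star
        mu <- mu_star
        ssr <- ssr_star
        acc["delta"] <- acc["delta"] + !in_burnin
        batch_acc["delta"] <- batch_acc["delta"] + 1
      }
    }

    # --- change-points: random-walk Metropolis on ordered support ---------
    if (!fix_cps) {
      for (j in seq_len(k)) {
        nm <- paste0("cp", j)
        batch_n[nm] <- batch_n[nm] + 1
        try_n[nm] <- try_n[nm] + !in_burnin
        c_star <- cps[j] + sd_cp[j] * stats::rnorm(1)
        lo <- if (j == 1) cp_lo else cps[j - 1]
        hi <- if (j == k) cp_hi else cps[j + 1]
        if (c_star <= lo || c_star >= hi) next
        if (n > 0 && (sum(ut < c_star) < 2 || sum(ut > c_star) < 2)) next
        h_star <- hinge(tt - c_star)
        # the next change-point's Uniform(cp_j, cp_hi) prior depends on cp_j
        lp_diff <- if (j < k) {
          log(cp_hi - cps[j]) - log(cp_hi - c_star)
        } else {
          0
        }
        d_mu <- (theta[2 + j] +
          if (use_ranef) b[ci, 2 + j] else 0) * (h_star - H[, j])
        mu_star <- mu + d_mu
        ssr_star <- if (n > 0) sum((y - mu_star)^2) else 0
        log_acc <- -0.5 * (ssr_star - ssr) / sigma2$eps + lp_diff
        if (log(stats::runif(1)) < log_acc) {
          cps[j] <- c_star
          H[, j] <- h_star
          mu <- mu_star
          ssr <- ssr_star
          acc[nm] <- acc[nm] + !in_burnin
          batch_acc[nm] <- batch_acc[nm] + 1
        }
      }
    }

    # --- proposal-scale adaptation during burn-in -------------------------
    if (control$adapt && in_burnin && iter %% 50 == 0) {
      rate_d <- batch_acc["delta"] / max(batch_n["delta"], 1)
      sd_delta <- min(max(sd_delta * exp(rate_d - 0.35), 1e-4), 25)
      for (j in seq_len(k)) {
        nm <- paste0("cp", j)
        rate_c <- batch_acc[nm] / max(batch_n[nm], 1)
        sd_cp[j] <- min(max(sd_cp[j] * exp(rate_c - 0.35), 1e-3), 25)
      }
      batch_acc[] <- 0
      batch_n[] <- 0
    }

    # --- retain -----------------------------------------------------------
    if (!in_burnin && (iter - control$burnin) %% control$thin == 0) {
      row <- row + 1L
      dev <- if (n > 0) n * log(2 * pi * sigma2$eps) + ssr / sigma2$eps else 0
      vals <- c(
        theta, delta, cps,
        sigma2$b0, sigma2$b1, sigma2$bcp, sigma2$b0S, sigma2$eps,
        if (use_ranef) as.vector(t(b)), dev
      )
      out[row, ] <- vals
    }
  }

  accept <- tibble::tibble(
    chain = chain,
    block = names(try_n),
    rate = ifelse(try_n > 0, acc / pmax(try_n, 1), NA_real_),
    scale = c(sd_delta, sd_cp)
  )
  list(draws = out, accept = accept)
}

#' @export
print.cp_fit <- function(x, ...) {
  cat("Bayesian change-point model fit (k =", x$spec$k, ")\n")
  cat(
    " ", x$control$chains, "chains x", x$control$iterations, "iterations;",
    "burn-in", x$control$burnin, "; thin", x$control$thin, "\n"
  )
  cat(
    " ", nrow(x$draws), "retained draws;", length(x$countries),
    "countries;", nrow(x$data), "observations\n"
  )
  invisible(x)
}
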