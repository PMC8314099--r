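quick_control <- function(seed = 5, ...) {
  cp_control(
    chains = 2, iterations = 600, burnin = 200, thin = 2, seed = seed, ...
  )
}

test_that("the same seed reproduces the draws exactly", {
  panel <- simulate_panel(n_countries = 3, t_max = 24, truth = default_truth(0),
    seed = 3
  )
  f1 <- cp_fit(panel, k = 0, control = quick_control())
  f2 <- cp_fit(panel, k = 0, control = quick_control())
  expect_identical(f1$draws, f2$draws)
  f3 <- cp_fit(panel, k = 0, control = quick_control(seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draws respect the protocol and the parameter support", {
  panel <- simulate_panel(n_countries = 4, t_max = 40, seed = 8)
  ctrl <- cp_control(chains = 2, iterations = 500, burnin = 150, thin = 3,
    seed = 2
  )
  fit <- cp_fit(panel, k = 2, control = ctrl)
  per_chain <- table(fit$draws$.chain)
  expect_equal(unname(as.integer(per_chain)), rep((500 - 150) %/% 3, 2))
  # ordered change-points and positive variances in every retained draw
  expect_true(all(fit$draws$cp1 < fit$draws$cp2))
  expect_true(all(fit$draws$cp1 >= 1 & fit$draws$cp2 <= 40))
  s2_cols <- grep("^sigma2_", names(fit$draws), value = TRUE)
  expect_true(all(as.matrix(fit$draws[s2_cols]) > 0))
  expect_true(all(is.finite(as.matrix(
    fit$draws[setdiff(names(fit$draws), c(".chain", ".iteration"))]
  ))))
})

test_that("every retained draw has a finite log posterior", {
  panel <- simulate_panel(n_countries = 3, t_max = 24, seed = 4)
  fit <- cp_fit(panel, k = 1, control = quick_control())
  priors <- fit$priors
  for (r in sample(nrow(fit$draws), 20)) {
    state <- commoncp:::state_from_draw(fit, r)
    lp <- log_prior(state, fit$spec, priors) +
      cp_loglik(panel, fit$spec, state)
    expect_true(is.finite(lp))
  }
})

test_that("with no data the sampler reproduces the prior", {
  empty <- as_panel(data.frame(
    country = character(0), time = integer(0), value = double(0)
  ))
  fit <- cp_fit(empty, k = 1, priors = cp_priors(cp_upper = 84),
    control = cp_control(
      chains = 2, iterations = 4000, burnin = 1000, thin = 2, seed = 7
    )
  )
  conv <- assess_convergence(fit)
  ess_c1 <- conv$ess[conv$term == "cp1"]
  se_c1 <- sd(fit$draws$cp1) / sqrt(ess_c1)
  expect_lt(abs(mean(fit$draws$cp1) - (1 + 84) / 2), 3 * se_c1)
  # coefficients are exact prior draws here
  expect_lt(abs(mean(fit$draws$beta0)), 3 * sqrt(1000 / nrow(fit$draws)))
})

test_that("clamped model matches the closed-form Gaussian posterior for the intercept", {
  # one country, no trend/season/random effects, known residual variance:
  # beta0 | y is Normal with precision n/s2 + 1/1000
  set.seed(123)
  n <- 40
  s2 <- 2.5
  y <- rnorm(n, 20, sqrt(s2))
  panel <- as_panel(data.frame(country = "BE", time = 1:n, value = y))
  fit <- cp_fit(panel, k = 0,
    priors = cp_priors(cp_upper = 84),
    control = cp_control(
      chains = 2, iterations = 10500, burnin = 500, thin = 1, seed = 9,
      fix = list(beta1 = 0, beta0S = 0, beta1S = 0, delta = 0,
        sigma2_eps = s2
      ),
      random_effects = FALSE
    )
  )
  prec <- n / s2 + 1 / 1000
  post_mean <- (sum(y) / s2) / prec
  post_var <- 1 / prec
  draws <- fit$draws$beta0
  m <- length(draws) # draws are iid here: exact conjugate conditional
  expect_lt(abs(mean(draws) - post_mean), 3 * sqrt(post_var / m))
  se_var <- post_var * sqrt(2 / (m - 1))
  expect_lt(abs(var(draws) - post_var), 3 * se_var)
  # clamped parameters never move
  expect_equal(unique(fit$draws$beta1), 0)
  expect_equal(unique(fit$draws$sigma2_eps), s2)
})

test_that("the residual-variance full conditional matches its analytic inverse-gamma", {
  set.seed(321)
  n <- 30
  y <- rnorm(n, 4, 1)
  panel <- as_panel(data.frame(country = "BE", time = 1:n, value = abs(y)))
  # clamp everything except sigma2_eps: its conditional is
  # IGamma(a + n/2, b + SSR/2) with fixed SSR
  fix <- list(beta0 = 4, beta1 = 0, beta0S = 0, beta1S = 0, delta = 0)
  fit <- cp_fit(panel, k = 0,
    priors = cp_priors(cp_upper = 84),
    control = cp_control(
      chains = 2, iterations = 10500, burnin = 500, thin = 1, seed = 13,
      fix = fix, random_effects = FALSE
    )
  )
  ssr <- sum((panel$value - 4)^2)
  a <- 0.001 + n / 2
  b <- 0.001 + ssr / 2
  true_mean <- b / (a - 1)
  true_var <- b^2 / ((a - 1)^2 * (a - 2))
  draws <- fit$draws$sigma2_eps
  m <- length(draws)
  expect_lt(abs(mean(draws) - true_mean), 3 * sqrt(true_var / m))
})

test_that("degenerate requests fail with diagnostic errors", {
  empty <- as_panel(data.frame(
    country = character(0), time = integer(0), value = double(0)
  ))
  expect_error(cp_fit(empty, k = 0), "cp_upper")
  narrow <- tiny_panel(times = 1:5)
  expect_error(
    cp_fit(narrow, k = 3, control = quick_control()),
    "reduce the number of change-points"
  )
  expect_error(cp_control(iterations = 100, burnin = 100), "burnin")
})

test_that("credible intervals cover the generating values across replicates", {
  # 20 independent panels at the default generating values; 95% equal-tail
  # intervals should cover the truth in at least 90% of replicates for the
  # intercept, amplitude trend, phase and both change-point locations
  truth_vals <- c(beta0 = 18.046, beta1S = -0.012, delta = 0.399,
    cp1 = 29, cp2 = 49)
  cover <- matrix(NA, 20, 5, dimnames = list(NULL, names(truth_vals)))
  for (rep in 1:20) {
    panel <- simulate_panel(n_countries = 10, t_max = 84, seed = 1000 + rep)
    fit <- cp_fit(panel, k = 2, control = cp_control(
      chains = 2, iterations = 3000, burnin = 1000, thin = 2, seed = rep
    ))
    for (p in names(truth_vals)) {
      q <- quantile(fit$draws[[p]], c(0.025, 0.975))
      cover[rep, p] <- truth_vals[p] >= q[1] && truth_vals[p] <= q[2]
    }
  }
  expect_true(all(colMeans(cover) >= 0.9))
})
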