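test_that("hinge is the positive part", {
  expect_equal(hinge(-3.2), 0)
  expect_equal(hinge(5.0), 5.0)
  expect_equal(hinge(0), 0)
  expect_equal(hinge(c(-1, 2)), c(0, 2))
})

test_that("an intercept-only state gives a flat mean", {
  state <- cp_state(beta0 = 17.784)
  spec <- cp_model(0)
  expect_equal(cp_mean(spec, state, c(1, 10, 84)), rep(17.784, 3))
})

test_that("the mean function matches a hand-evaluated sum of its four terms", {
  p <- model3_fixed
  state <- cp_state(
    beta0 = p$beta0, beta1 = p$beta1, beta_cp = c(p$beta2, p$beta3),
    beta0S = p$beta0S, beta1S = p$beta1S, delta = p$delta,
    cps = c(p$c1, p$c2),
    sigma2 = list(b0 = 1, b1 = 1, bcp = c(1, 1), b0S = 1, eps = 1)
  )
  t <- 10
  # independent literal evaluation, term by term
  expected <- p$beta0 +
    p$beta1 * t +
    p$beta2 * max(t - p$c1, 0) + p$beta3 * max(t - p$c2, 0) +
    (p$beta0S + p$beta1S * t) * sin(pi / 2 * t + p$delta)
  expect_equal(cp_mean(cp_model(2), state, t), expected, tolerance = 1e-12)

  # and at a time after both change-points, where both hinges are active
  t2 <- 60
  expected2 <- p$beta0 + p$beta1 * t2 +
    p$beta2 * (t2 - p$c1) + p$beta3 * (t2 - p$c2) +
    (p$beta0S + p$beta1S * t2) * sin(pi / 2 * t2 + p$delta)
  expect_equal(cp_mean(cp_model(2), state, t2), expected2, tolerance = 1e-12)
})

test_that("before the first change-point the model nests the no-change-point model", {
  p <- model3_fixed
  with_cp <- cp_state(
    beta0 = p$beta0, beta1 = p$beta1, beta_cp = c(p$beta2, p$beta3),
    beta0S = p$beta0S, beta1S = p$beta1S, delta = p$delta,
    cps = c(p$c1, p$c2),
    sigma2 = list(b0 = 1, b1 = 1, bcp = c(1, 1), b0S = 1, eps = 1)
  )
  without <- cp_state(
    beta0 = p$beta0, beta1 = p$beta1,
    beta0S = p$beta0S, beta1S = p$beta1S, delta = p$delta
  )
  t <- seq(1, 28, by = 0.5) # all below c1 = 29.028
  expect_equal(
    cp_mean(cp_model(2), with_cp, t),
    cp_mean(cp_model(0), without, t)
  )

  # zero slope differences nest exactly at every time
  null_cp <- with_cp
  null_cp$beta_cp <- c(0, 0)
  t_all <- seq(1, 84, by = 0.25)
  expect_equal(
    cp_mean(cp_model(2), null_cp, t_all),
    cp_mean(cp_model(0), without, t_all)
  )
})

test_that("the mean function is continuous at each change-point", {
  state <- oracle_state(k = 2)
  spec <- cp_model(2)
  gap_at <- function(cp, eps) {
    abs(
      cp_mean(spec, state, cp + eps, country = "BE") -
        cp_mean(spec, state, cp - eps, country = "BE")
    )
  }
  for (cp in state$cps) {
    eps <- c(1e-4, 1e-6, 1e-8)
    gaps <- vapply(eps, function(e) gap_at(cp, e), 0)
    # no jump: the gap is bounded by the local slope (< 20 per quarter)
    # times the window width, so it vanishes linearly with the window
    expect_true(all(gaps < 20 * 2 * eps))
  }
})

test_that("the seasonal factor has period 4 and drifts only through the amplitude trend", {
  omega <- cp_model(0, period = 4)$omega
  delta <- 0.4
  t <- seq(1, 80, by = 0.1)
  expect_equal(sin(omega * t + delta), sin(omega * (t + 4) + delta),
    tolerance = 1e-12
  )
  state <- oracle_state(0)
  spec <- cp_model(0)
  # with beta1S = 0 and beta1 = 0 the mean is exactly 4-periodic
  flat <- state
  flat$beta1S <- 0
  flat$beta1 <- 0
  flat$ranef$b1 <- 0
  expect_equal(
    cp_mean(spec, flat, t, country = "BE"),
    cp_mean(spec, flat, t + 4, country = "BE"),
    tolerance = 1e-10
  )
})

test_that("log-likelihood matches a per-point brute-force oracle", {
  state <- oracle_state(k = 2)
  spec <- cp_model(2)
  panel <- tiny_panel(times = c(1, 5, 12, 25))
  # brute force: one dnorm per record, evaluated independently
  brute <- 0
  for (r in seq_len(nrow(panel))) {
    mu_r <- cp_mean(spec, state, panel$time[r], country = panel$country[r])
    brute <- brute +
      log(1 / sqrt(2 * pi * state$sigma2$eps)) -
      (panel$value[r] - mu_r)^2 / (2 * state$sigma2$eps)
  }
  expect_equal(cp_loglik(panel, spec, state), brute, tolerance = 1e-10)
})

test_that("log-likelihood is additive and deviance is -2 times it", {
  state <- oracle_state(0)
  spec <- cp_model(0)
  one <- tiny_panel(countries = "BE", times = 1:4)
  # an identical second country doubles the log-likelihood
  both <- tiny_panel(countries = c("BE", "NL"), times = 1:4)
  sym <- state
  sym$ranef[] <- lapply(sym$ranef, function(x) {
    if (is.numeric(x)) rep(x[1], length(x)) else x
  })
  sym$ranef$country <- c("BE", "NL")
  expect_equal(cp_loglik(both, spec, sym), 2 * cp_loglik(one, spec, sym))
  expect_equal(cp_deviance(both, spec, sym), -2 * cp_loglik(both, spec, sym))
  # permuting record order changes nothing
  shuffled <- both[rev(seq_len(nrow(both))), ]
  expect_equal(cp_deviance(shuffled, spec, sym), cp_deviance(both, spec, sym))
})

test_that("a single observation at its mean with variance 1/(2*pi) has log-likelihood 0", {
  state <- cp_state(
    beta0 = 5,
    sigma2 = list(b0 = 1, b1 = 1, bcp = numeric(0), b0S = 1, eps = 1 / (2 * pi))
  )
  panel <- as_panel(data.frame(country = "BE", time = 1, value = 5 +
    cp_mean(cp_model(0), state, 1) - state$beta0))
  expect_equal(cp_loglik(panel, cp_model(0), state), 0, tolerance = 1e-12)
  bad <- state
  bad$sigma2$eps <- -1
  expect_error(cp_loglik(panel, cp_model(0), bad), "> 0")
})

test_that("state constructor enforces internal consistency", {
  expect_error(cp_state(beta_cp = 0.1), "same length")
  expect_error(cp_state(beta_cp = c(1, 2), cps = c(30, 20),
    sigma2 = list(b0 = 1, b1 = 1, bcp = c(1, 1), b0S = 1, eps = 1)
  ), "increasing")
  expect_error(cp_mean(cp_model(1), cp_state(), 5), "disagree")
  expect_error(
    cp_mean(cp_model(0), oracle_state(0), 5, country = "XX"),
    "unknown country"
  )
})
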