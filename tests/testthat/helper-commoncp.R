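# Shared builders for tiny in-code fixtures.

# small balanced panel with a known deterministic structure
tiny_panel <- function(countries = c("BE", "NL"), times = 1:4,
                       value_fun = function(country, time) 10 + time) {
  grid <- expand.grid(
    country = countries, time = times,
    stringsAsFactors = FALSE
  )
  grid$value <- mapply(value_fun, grid$country, grid$time)
  as_panel(grid)
}

# a fully specified two-country state for oracle checks
oracle_state <- function(k = 0) {
  ranef <- tibble::tibble(
    country = c("BE", "NL"),
    b0 = c(1.5, -0.7), b1 = c(0.02, -0.01), b0S = c(0.3, -0.2)
  )
  for (j in seq_len(k)) {
    ranef[[paste0("bcp", j)]] <- c(0.05, -0.03) / j
  }
  cp_state(
    beta0 = 17, beta1 = 0.05,
    beta_cp = if (k > 0) seq(0.1, by = 0.05, length.out = k) else numeric(0),
    beta0S = 3.5, beta1S = -0.01, delta = 0.4,
    cps = if (k > 0) seq(10, by = 10, length.out = k) else numeric(0),
    ranef = ranef,
    sigma2 = list(
      b0 = 40, b1 = 0.01, bcp = rep(0.03, k), b0S = 2.5, eps = 1.6
    )
  )
}

# Table-1-magnitude fixed effects, used in several mean-function checks
model3_fixed <- list(
  beta0 = 18.046, beta1 = -0.017, beta2 = 0.054, beta3 = -0.051,
  c1 = 29.028, c2 = 48.839, beta0S = 3.808, beta1S = -0.012, delta = 0.399
)
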