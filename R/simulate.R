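#' Generating values for a two-change-point consumption panel
#'
#' Population-level parameter values in the magnitude regime of European
#' community antibiotic consumption (DDD per 1000 inhabitants per day):
#' intercept near 18, a slightly negative underlying trend, slope shifts of
#' about +0.05 and -0.05 per quarter at change-points placed at quarters 29
#' and 49 (the change-point locations are rounded to whole quarters for
#' clean simulation bookkeeping), a seasonal amplitude near 3.8 slowly
#' shrinking over time, and substantial between-country intercept
#' heterogeneity.
#'
#' @param k Number of change-points, 0, 1 or 2; smaller `k` drops the later
#'   change-point terms.
#' @return A [cp_state()] with `ranef = NULL` (random effects are drawn per
#'   simulated country by [simulate_panel()]).
#' @export
default_truth <- function(k = 2) {
  if (!k %in% 0:2) {
    stop("`k` must be 0, 1 or 2 for the built-in generating values.",
      call. = FALSE
    )
  }
  beta_cp <- c(0.054, -0.051)[seq_len(k)]
  cps <- c(29, 49)[seq_len(k)]
  s2_bcp <- c(0.029, 0.042)[seq_len(k)]
  cp_state(
    beta0 = 18.046, beta1 = -0.017, beta_cp = beta_cp,
    beta0S = 3.808, beta1S = -0.012, delta = 0.399,
    cps = cps, ranef = NULL,
    sigma2 = list(
      b0 = 40.711, b1 = 0.007, bcp = s2_bcp, b0S = 2.572, eps = 1.646
    )
  )
}

#' Simulate an unbalanced quarterly consumption panel
#'
#' Generates data with the exact statistical structure of the fitted model:
#' country random effects drawn from zero-mean normals with the configured
#' variance components, means from the piecewise-linear-plus-seasonal mean
#' function, and independent Gaussian noise. Three missingness motifs of
#' surveillance panels are then applied, each completely at random: late
#' entry (a country's initial block of quarters is absent), intermittent
#' gaps (each remaining cell independently dropped), and right truncation
#' (recent quarters not yet submitted). Negative simulated values are kept
#' by default — the fitted model is also Gaussian, and truncation would bias
#' parameter-recovery experiments; set `clip_negative = TRUE` for
#' display-quality panels.
#'
#' @param n_countries Number of countries (default 25).
#' @param t_max Number of quarters in the study window (default 84).
#' @param truth A [cp_state()] of generating values with `ranef = NULL`;
#'   defaults to [default_truth()] with two change-points.
#' @param late_entry_fraction Probability a country enters late (default 0.4).
#' @param late_entry_max_delay Maximum late-entry delay in quarters
#'   (default 40); the realised delay is uniform on 1..max.
#' @param intermittent_missing_rate Per-cell independent drop probability
#'   (default 0.05).
#' @param right_truncation_fraction Probability a country's recent quarters
#'   are missing (default 0.2).
#' @param right_truncation_max_length Maximum truncated tail length in
#'   quarters (default 12); uniform on 1..max.
#' @param clip_negative Replace negative simulated values by 0 (default
#'   `FALSE`; display only — leave `FALSE` for inference experiments).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param origin Calendar anchor of time index 1.
#' @param period Quarters per seasonal cycle.
#'
#' @return A `cp_panel` tibble with attributes `truth` (the complete
#'   generating [cp_state()], drawn random effects included; see
#'   [panel_truth()]) and `origin`.
#' @examples
#' panel <- simulate_panel(n_countries = 5, t_max = 40, seed = 42)
#' panel_truth(panel)$cps
#' @export
simulate_panel <- function(n_countries = 25, t_max = 84,
                           truth = default_truth(),
                           late_entry_fraction = 0.4,
                           late_entry_max_delay = 40,
                           intermittent_missing_rate = 0.05,
                           right_truncation_fraction = 0.2,
                           right_truncation_max_length = 12,
                           clip_negative = FALSE,
                           seed = NULL,
                           origin = calendar_quarter(1997, 1),
                           period = 4) {
  if (t_max < 8) {
    stop("`t_max` must be >= 8.", call. = FALSE)
  }
  probs <- c(late_entry_fraction, intermittent_missing_rate,
             right_truncation_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("missingness probabilities must be in [0, 1].", call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  k <- state_k(truth)
  spec <- cp_model(k = k, period = period)
  s2 <- truth$sigma2

  countries <- sprintf("C%02d", seq_len(n_countries))
  ranef <- tibble::tibble(
    country = countries,
    b0 = stats::rnorm(n_countries, 0, sqrt(s2$b0)),
    b1 = stats::rnorm(n_countries, 0, sqrt(s2$b1)),
    b0S = stats::rnorm(n_countries, 0, sqrt(s2$b0S))
  )
  for (j in seq_len(k)) {
    ranef[[paste0("bcp", j)]] <- stats::rnorm(n_countries, 0, sqrt(s2$bcp[j]))
  }
  full_truth <- truth
  full_truth$ranef <- ranef

  grid <- tidyr::expand_grid(country = countries, time = seq_len(t_max))
  mu <- numeric(nrow(grid))
  for (cc in countries) {
    sel <- grid$country == cc
    mu[sel] <- cp_mean(spec, full_truth, grid$time[sel], country = cc)
  }
  grid$value <- mu + stats::rnorm(nrow(grid), 0, sqrt(s2$eps))

  keep <- rep(TRUE, nrow(grid))
  for (i in seq_len(n_countries)) {
    sel <- grid$country == countries[i]
    if (late_entry_fraction > 0 &&
          stats::runif(1) < late_entry_fraction && late_entry_max_delay >= 1) {
      delay <- sample.int(late_entry_max_delay, 1)
      keep[sel & grid$time <= delay] <- FALSE
    }
    if (right_truncation_fraction > 0 &&
          stats::runif(1) < right_truncation_fraction &&
          right_truncation_max_length >= 1) {
      cut <- sample.int(right_truncation_max_length, 1)
      keep[sel & grid$time > t_max - cut] <- FALSE
    }
  }
  if (intermittent_missing_rate > 0) {
    keep <- keep & (stats::runif(nrow(grid)) >= intermittent_missing_rate)
  }
  grid <- grid[keep, ]
  if (clip_negative) {
    grid$value <- pmax(grid$value, 0)
  }

  panel <- as_panel(grid, origin = origin, allow_negative = !clip_negative)
  attr(panel, "truth") <- full_truth
  panel
}

#' Ground truth attached to a simulated panel
#'
#' @param panel A panel produced by [simulate_panel()].
#' @return The generating [cp_state()], drawn random effects included.
#' @export
panel_truth <- function(panel) {
  truth <- attr(panel, "truth")
  if (is.null(truth)) {
    stop("this panel carries no simulation ground truth.", call. = FALSE)
  }
  truth
}
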