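#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

# inverse-gamma log-density, shape/rate: density ~ x^-(a+1) exp(-b/x)
dinvgamma_log <- function(x, shape, rate) {
  ifelse(
    x > 0,
    shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
    -Inf
  )
}

rinvgamma <- function(n, shape, rate) {
  g <- stats::rgamma(n, shape = shape, rate = rate)
  # At very small shapes (the 0.001 "uninformative" prior) the Gamma draw can
  # underflow to 0, which would return an infinite variance; redraw those.
  # This truncates the inverse-gamma tail at the largest representable
  # double, a distortion only for variances beyond ~1e300.
  x <- 1 / g
  bad <- which(!is.finite(x) | x <= 0)
  while (length(bad) > 0) {
    x[bad] <- 1 / stats::rgamma(length(bad), shape = shape, rate = rate)
    bad <- bad[!is.finite(x[bad]) | x[bad] <= 0]
  }
  x
}
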