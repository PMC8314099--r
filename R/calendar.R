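#' Calendar quarter
#'
#' A lightweight (year, quarter) pair used to anchor the model's integer time
#' index to real calendar time. Time index 1 corresponds to `origin`; each
#' unit step is one quarter.
#'
#' @param year Integer calendar year.
#' @param quarter Integer quarter, 1--4.
#'
#' @return A tibble with columns `year` and `quarter` of class `cal_quarter`.
#' @examples
#' calendar_quarter(1997, 1)
#' @export
calendar_quarter <- function(year, quarter) {
  if (!all(is.finite(year)) || !all(year == floor(year))) {
    stop("`year` must be an integer.", call. = FALSE)
  }
  if (!all(quarter %in% 1:4)) {
    stop("`quarter` must be in 1, 2, 3, 4.", call. = FALSE)
  }
  out <- tibble::tibble(year = as.integer(year), quarter = as.integer(quarter))
  class(out) <- c("cal_quarter", class(out))
  out
}

# absolute quarter count since year 0 (internal common currency)
abs_quarter <- function(q) q$year * 4L + (q$quarter - 1L)

#' Map a (possibly fractional) time index to its calendar quarter
#'
#' Posterior means of change-point locations are fractional time indices
#' (e.g. 44.529). They are mapped to calendar quarters by taking the floor of
#' the index: index 44.529 falls inside quarter 44, which with origin 1997 Q1
#' is the last quarter of 2007. Rounding would instead give 2008 Q1 and is not
#' used.
#'
#' @param t Numeric vector of time indices, each >= 1.
#' @param origin A [calendar_quarter()] anchoring time index 1 (default
#'   1997 Q1).
#'
#' @return A tibble with columns `year` and `quarter`, one row per element of
#'   `t`.
#' @examples
#' time_index_to_quarter(44.529) # 2007 Q4
#' time_index_to_quarter(29.028) # 2004 Q1
#' @export
time_index_to_quarter <- function(t, origin = calendar_quarter(1997, 1)) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 1)) {
    stop("time indices must be finite and >= 1.", call. = FALSE)
  }
  a <- abs_quarter(origin) + (floor(t) - 1)
  calendar_quarter(a %/% 4, a %% 4 + 1)
}

#' Map a calendar quarter to its integer time index
#'
#' Exact inverse of [time_index_to_quarter()] on integer indices.
#'
#' @param q A [calendar_quarter()] (vectorised over its rows).
#' @param origin A [calendar_quarter()] anchoring time index 1.
#'
#' @return Integer vector of time indices (>= 1).
#' @examples
#' quarter_to_time_index(calendar_quarter(2017, 4)) # 84
#' @export
quarter_to_time_index <- function(q, origin = calendar_quarter(1997, 1)) {
  t <- abs_quarter(q) - abs_quarter(origin) + 1L
  if (any(t < 1L)) {
    stop("quarter precedes the origin of the time index.", call. = FALSE)
  }
  as.integer(t)
}

#' Format a time index as a calendar label
#'
#' @param t Numeric vector of time indices.
#' @param origin A [calendar_quarter()].
#' @return Character vector like `"2004 Q1"`.
#' @export
format_quarter <- function(t, origin = calendar_quarter(1997, 1)) {
  q <- time_index_to_quarter(t, origin)
  sprintf("%d Q%d", q$year, q$quarter)
}
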