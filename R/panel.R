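#' Build a validated consumption panel from a data frame
#'
#' A panel is a long table with one record per (country, quarter): columns
#' `country`, `time` (integer quarterly index, 1 = `origin`) and `value`
#' (consumption in DDD per 1000 inhabitants per day). Series may be
#' unbalanced: countries can enter late, miss intermittent quarters, or stop
#' reporting early; missing quarters are simply absent rows, never sentinel
#' values.
#'
#' @param data A data frame with columns `country`, `value` and either `time`
#'   (or `time_index`) or the pair `year`, `quarter`.
#' @param origin A [calendar_quarter()] anchoring time index 1 (default
#'   1997 Q1).
#' @param allow_negative Accept negative values. Real consumption is
#'   non-negative and negative values in input files are rejected; the
#'   Gaussian simulator sets this to keep rare negative draws, which
#'   truncation would otherwise bias.
#'
#' @return A tibble of class `cp_panel` with columns `country` (character),
#'   `time` (integer) and `value` (double), sorted by country then time, and
#'   an `origin` attribute. Rows with missing `value` are dropped with a
#'   message.
#' @examples
#' as_panel(data.frame(country = "BE", time = 1:3, value = c(10, 12, 11)))
#' @export
as_panel <- function(data, origin = calendar_quarter(1997, 1),
                     allow_negative = FALSE) {
  data <- tibble::as_tibble(data)
  if (!"country" %in% names(data)) {
    stop("panel data needs a `country` column.", call. = FALSE)
  }
  if (!"value" %in% names(data)) {
    stop("panel data needs a `value` column.", call. = FALSE)
  }
  if ("time_index" %in% names(data) && !"time" %in% names(data)) {
    data <- dplyr::rename(data, time = "time_index")
  }
  if (!"time" %in% names(data)) {
    if (!all(c("year", "quarter") %in% names(data))) {
      stop("panel data needs either a `time` column or `year` and `quarter` columns.",
        call. = FALSE
      )
    }
    if (!all(data$quarter %in% 1:4)) {
      bad <- unique(data$quarter[!data$quarter %in% 1:4])
      stop("`quarter` outside 1-4: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    data$time <- quarter_to_time_index(
      calendar_quarter(data$year, data$quarter), origin
    )
  }

  n_missing <- sum(is.na(data$value))
  if (n_missing > 0) {
    message("Dropping ", n_missing, " row(s) with missing `value`.")
    data <- data[!is.na(data$value), ]
  }

  out <- dplyr::transmute(data,
    country = as.character(.data$country),
    time = as.integer(.data$time),
    value = as.double(.data$value)
  )

  if (any(!is.finite(out$value))) {
    stop("panel values must be finite.", call. = FALSE)
  }
  if (!allow_negative && any(out$value < 0)) {
    stop("panel values must be >= 0 (DDD per 1000 inhabitants per day).",
      call. = FALSE
    )
  }
  if (any(is.na(out$time)) || any(out$time < 1)) {
    stop("time indices must be integers >= 1.", call. = FALSE)
  }
  dup <- duplicated(out[c("country", "time")])
  if (any(dup)) {
    first <- out[dup, ][1, ]
    stop("duplicate (country, time) record: (", first$country, ", ",
      first$time, ").",
      call. = FALSE
    )
  }

  out <- dplyr::arrange(out, .data$country, .data$time)
  attr(out, "origin") <- origin
  class(out) <- c("cp_panel", class(out))
  out
}

#' Read a long-format consumption panel from CSV
#'
#' Accepts either header `country,year,quarter,value` or
#' `country,time,value` (`time_index` is accepted as a synonym for `time`).
#'
#' @inheritParams as_panel
#' @param path Path to a CSV file (UTF-8, decimal point).
#' @return A validated `cp_panel` tibble; see [as_panel()].
#' @export
read_panel <- function(path, origin = calendar_quarter(1997, 1)) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_panel(data, origin)
}

#' Write a panel back to CSV
#'
#' Writes the `country,time,value` dialect; reading the file back with
#' [read_panel()] reproduces the record set exactly.
#'
#' @param panel A `cp_panel` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel[c("country", "time", "value")], path, progress = FALSE)
  invisible(path)
}

panel_origin <- function(panel) {
  attr(panel, "origin") %||% calendar_quarter(1997, 1)
}

#' @export
print.cp_panel <- function(x, ...) {
  n_c <- dplyr::n_distinct(x$country)
  cat(
    "# Consumption panel:", nrow(x), "records,", n_c, "countries, quarters",
    min(x$time), "-", max(x$time), "\n"
  )
  NextMethod()
}
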