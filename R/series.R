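#' Monthly concentration (or rate) series
#'
#' The universal exchange type between pipeline stages: one value per
#' contiguous calendar month, each value representing the last day of its
#' month.  Missing months are explicit `NA`s, never zeros — a month in which a
#' well pumped no water is *unknown* at the tap, not clean.
#'
#' @param start `month_index` of the first month.
#' @param values Numeric vector (one per month); `NA` marks missing.
#'   Non-missing values must be >= 0.
#' @param units Unit label carried for display (default `"ug/L"`).
#' @return A `monthly_series` object.
#' @export
monthly_series <- function(start, values, units = "ug/L") {
  start <- as_month_index_like(start)
  if (length(start) != 1L) stop("monthly_series: start must be a single month")
  values <- as.numeric(values)
  if (length(values) < 1L) stop("monthly_series: needs at least one month")
  if (any(values < 0, na.rm = TRUE))
    stop("monthly_series: negative values are not allowed")
  structure(list(start = start, values = values, units = units),
            class = "monthly_series")
}

#' @export
length.monthly_series <- function(x) length(x$values)

#' Months covered by a monthly series
#' @param x A `monthly_series`.
#' @return `month_index` vector, one entry per value.
#' @export
series_months <- function(x) month_add(x$start, seq_along(x$values) - 1L)

#' Look up series values for given months
#'
#' @param x A `monthly_series`.
#' @param months `month_index` vector (or "YYYY-MM" stamps).
#' @return Numeric vector; `NA` for months outside the series.
#' @export
series_get <- function(x, months) {
  months <- as_month_index_like(months)
  idx <- month_diff(months, x$start) + 1L
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1L & idx <= length(x$values)
  out[ok] <- x$values[idx[ok]]
  out
}

#' Restrict a series to an inclusive month window
#' @param x A `monthly_series`.
#' @param from,to `month_index` scalars (window clipped to the series).
#' @return A `monthly_series`.
#' @export
series_window <- function(x, from, to) {
  from <- as_month_index_like(from); to <- as_month_index_like(to)
  i0 <- max(1L, month_diff(from, x$start) + 1L)
  i1 <- min(length(x$values), month_diff(to, x$start) + 1L)
  if (i0 > i1) stop("series_window: empty window")
  monthly_series(month_add(x$start, i0 - 1L), x$values[i0:i1], units = x$units)
}

#' @export
print.monthly_series <- function(x, ...) {
  m <- series_months(x)
  cat(sprintf("<monthly_series> %s .. %s (%d months, %s)\n",
              format(m[1L]), format(m[length(m)]), length(x$values), x$units))
  n_miss <- sum(is.na(x$values))
  cat(sprintf("  range %.4g .. %.4g, %d missing\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)), n_miss))
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(month = format(series_months(x)), value = x$values,
             stringsAsFactors = FALSE)
}

#' Peak value and month of a monthly series
#' @param x A `monthly_series`.
#' @return List with `value` and `month` (`month_index`); `NA`s ignored.
#' @export
series_peak <- function(x) {
  if (all(is.na(x$values))) return(list(value = NA_real_, month = x$start[0L]))
  i <- which.max(x$values)
  list(value = x$values[i], month = month_add(x$start, i - 1L))
}
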