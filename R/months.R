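#' Monthly calendar index
#'
#' The whole pipeline runs on a monthly clock.  A `month_index` is stored as a
#' serial month count (`year * 12 + month - 1`), which makes ordering and
#' month arithmetic exact.  A value attached to a `month_index` represents the
#' state on the *last day* of that month: monthly concentration snapshots are
#' taken at the end of the month and interpreted as the mean for that month.
#'
#' @param year Integer calendar year(s).
#' @param month Integer month(s) in 1--12.
#' @return A `month_index` vector.
#' @examples
#' month_index(1972, 7)
#' month_range(month_index(1984, 12), month_index(1985, 1))
#' @export
month_index <- function(year, month) {
  if (length(year) != length(month)) {
    n <- max(length(year), length(month))
    year <- rep_len(year, n)
    month <- rep_len(month, n)
  }
  year <- as.integer(year)
  month <- as.integer(month)
  if (anyNA(year) || anyNA(month)) stop("month_index: year/month must not be NA")
  if (any(month < 1L | month > 12L)) stop("month_index: month must be in 1..12")
  new_month_index(year * 12L + (month - 1L))
}

new_month_index <- function(serial) {
  structure(as.integer(serial), class = "month_index")
}

#' Parse "YYYY-MM" month stamps
#'
#' @param x Character vector of ISO month stamps (`"1972-07"`), or a
#'   `month_index` (returned unchanged).
#' @return A `month_index` vector.
#' @export
as_month_index <- function(x) {
  if (inherits(x, "month_index")) return(x)
  if (is.character(x)) {
    ok <- grepl("^-?[0-9]{1,4}-[0-9]{2}$", x)
    if (!all(ok)) stop("as_month_index: expected 'YYYY-MM' stamps, got: ",
                       paste(utils::head(x[!ok], 3L), collapse = ", "))
    y <- as.integer(sub("-[0-9]{2}$", "", x))
    m <- as.integer(sub("^-?[0-9]{1,4}-", "", x))
    return(month_index(y, m))
  }
  stop("as_month_index: cannot convert object of class ", class(x)[1L])
}

#' @export
format.month_index <- function(x, ...) {
  sprintf("%04d-%02d", month_year(x), month_of(x))
}

#' @export
print.month_index <- function(x, ...) {
  cat("<month_index> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.month_index <- function(x, ...) format(x)

#' @export
`[.month_index` <- function(x, i) new_month_index(unclass(x)[i])

#' @export
c.month_index <- function(...) {
  parts <- lapply(list(...), function(p) unclass(as_month_index_like(p)))
  new_month_index(unlist(parts))
}

as_month_index_like <- function(x) {
  if (inherits(x, "month_index")) x else as_month_index(x)
}

#' @export
unique.month_index <- function(x, ...) new_month_index(unique(unclass(x)))

#' Calendar components of a month index
#'
#' @param m A `month_index`.
#' @return Integer vector of calendar years (`month_year`) or months 1--12
#'   (`month_of`).
#' @export
month_year <- function(m) unclass(m) %/% 12L

#' @rdname month_year
#' @export
month_of <- function(m) unclass(m) %% 12L + 1L

#' Month arithmetic
#'
#' `month_add` shifts by whole months; `month_diff` is the signed difference
#' `a - b` in months (0 for the same month).
#'
#' @param m,a,b `month_index` values.
#' @param k Integer number of months.
#' @return `month_index` (`month_add`) or integer (`month_diff`).
#' @export
month_add <- function(m, k) new_month_index(unclass(m) + as.integer(k))

#' @rdname month_add
#' @export
month_diff <- function(a, b) unclass(a) - unclass(b)

#' Inclusive contiguous month range
#'
#' @param start,end `month_index` scalars with `start <= end`.
#' @return `month_index` vector of length `month_diff(end, start) + 1`.
#' @export
month_range <- function(start, end) {
  start <- as_month_index_like(start); end <- as_month_index_like(end)
  if (length(start) != 1L || length(end) != 1L)
    stop("month_range: start and end must be scalars")
  if (unclass(start) > unclass(end))
    stop("month_range: start (", format(start), ") is after end (", format(end), ")")
  new_month_index(seq.int(unclass(start), unclass(end)))
}

#' Days and hours in a calendar month
#'
#' Used to convert between monthly rates and event-hour accounting.
#'
#' @param m A `month_index`.
#' @return Integer days (`days_in_month`) or hours (`hours_in_month`).
#' @export
days_in_month <- function(m) {
  y <- month_year(m); mo <- month_of(m)
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[mo]
  leap <- (y %% 4L == 0L & y %% 100L != 0L) | (y %% 400L == 0L)
  base + ifelse(mo == 2L & leap, 1L, 0L)
}

#' @rdname days_in_month
#' @export
hours_in_month <- function(m) 24L * days_in_month(m)
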