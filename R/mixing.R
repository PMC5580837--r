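#' Flow-weighted mixing of well water at the treatment plant
#'
#' Materials mass-balance mixing: the treated-water concentration each month
#' is the pumping-weighted mean over the wells delivering water that month,
#' `C_wtp(m) = sum(Q_i * C_i) / sum(Q_i)` over wells with `Q_i > 0`.  No
#' treatment removal is applied: the mixed concentration is taken to
#' represent drinking water throughout the plant's service area.  Months in
#' which no well pumps are missing (`NA`), never zero.
#'
#' @param schedule A [pumping_schedule()].
#' @param well_conc A `well_conc_series` from [extract_well_series()] (named
#'   list of [monthly_series], one per well).
#' @return A `wtp_series`: list with `series` (a [monthly_series]) and
#'   `provenance` (months x wells matrix of delivered-water shares, rows
#'   summing to 1 in mixing months).
#' @export
mix_at_wtp <- function(schedule, well_conc) {
  months <- schedule_months(schedule)
  ids <- colnames(schedule$rates)
  vals <- rep(NA_real_, length(months))
  prov <- matrix(0, length(months), length(ids),
                 dimnames = list(format(months), ids))
  for (i in seq_along(months)) {
    q <- schedule$rates[i, ]
    on <- which(q > 0)
    if (length(on) == 0L) next
    cc <- vapply(on, function(j) {
      s <- well_conc[[ids[j]]]
      if (is.null(s)) stop("mix_at_wtp: no concentration series for well '",
                           ids[j], "'")
      series_get(s, months[i])
    }, 1.0)
    if (anyNA(cc)) {
      bad <- ids[on[which(is.na(cc))[1L]]]
      stop("mix_at_wtp: well '", bad, "' pumps in ", format(months[i]),
           " but its concentration is missing")
    }
    vals[i] <- sum(q[on] * cc) / sum(q[on])
    prov[i, on] <- q[on] / sum(q[on])
  }
  structure(list(series = monthly_series(months[1L], vals), provenance = prov),
            class = "wtp_series")
}

#' @export
print.wtp_series <- function(x, ...) {
  cat("<wtp_series>\n"); print(x$series); invisible(x)
}

#' Find MCL-exceedance periods in a monthly series
#'
#' Maximal runs of consecutive months whose value strictly exceeds the MCL.
#' A value exactly equal to the MCL is not an exceedance, and missing months
#' break runs.
#'
#' @param series A [monthly_series].
#' @param mcl Maximum contaminant level, ug/L, > 0.
#' @return data.frame with columns `start`, `end` ("YYYY-MM"), `n_months`,
#'   `mcl`, in chronological order (zero rows if never exceeded).
#' @export
find_exceedances <- function(series, mcl) {
  if (!is.numeric(mcl) || length(mcl) != 1L || mcl <= 0)
    stop("find_exceedances: mcl must be a single value > 0")
  ex <- !is.na(series$values) & series$values > mcl
  months <- series_months(series)
  r <- rle(ex)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = format(months[starts[keep]]),
             end = format(months[ends[keep]]),
             n_months = r$lengths[keep],
             mcl = rep(mcl, length(keep)),
             stringsAsFactors = FALSE)
}
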