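#' Monthly per-well pumping schedule
#'
#' Rates are m3/day, extraction positive, one row per month and one column
#' per well; zero outside a well's service intervals.
#'
#' @param start `month_index` of the first row.
#' @param rates Numeric matrix (months x wells) with well ids as column names.
#' @return A `pumping_schedule` object.
#' @export
pumping_schedule <- function(start, rates) {
  start <- as_month_index_like(start)
  rates <- as.matrix(rates)
  if (is.null(colnames(rates))) stop("pumping_schedule: rates needs well-id column names")
  if (any(rates < 0)) stop("pumping_schedule: rates must be >= 0")
  structure(list(start = start, rates = rates), class = "pumping_schedule")
}

#' @export
print.pumping_schedule <- function(x, ...) {
  m <- schedule_months(x)
  cat(sprintf("<pumping_schedule> %d wells, %s .. %s\n", ncol(x$rates),
              format(m[1L]), format(m[length(m)])))
  invisible(x)
}

#' Months covered by a pumping schedule
#' @param schedule A `pumping_schedule`.
#' @return `month_index` vector.
#' @export
schedule_months <- function(schedule)
  month_add(schedule$start, seq_len(nrow(schedule$rates)) - 1L)

#' Per-well rates for one month
#' @param schedule A `pumping_schedule`.
#' @param month A `month_index` scalar.
#' @return Named numeric vector (m3/day); `NA`s for months outside the schedule.
#' @export
schedule_rates <- function(schedule, month) {
  i <- month_diff(as_month_index_like(month), schedule$start) + 1L
  if (i < 1L || i > nrow(schedule$rates))
    return(setNames(rep(NA_real_, ncol(schedule$rates)), colnames(schedule$rates)))
  setNames(schedule$rates[i, ], colnames(schedule$rates))
}

#' In-service table for a set of wells
#'
#' @param wells List of [well_record()]s.
#' @param clock `month_index` vector (e.g. [site_clock()]).
#' @return Logical matrix (months x wells), `TRUE` exactly inside service
#'   intervals (inclusive of both endpoint months).
#' @export
service_matrix <- function(wells, clock) {
  clock <- as_month_index_like(clock)
  serial <- unclass(clock)
  out <- matrix(FALSE, length(serial), length(wells),
                dimnames = list(format(clock),
                                vapply(wells, function(w) w$id, "")))
  for (j in seq_along(wells)) {
    for (iv in wells[[j]]$service_intervals) {
      out[serial >= unclass(iv$start) & serial <= unclass(iv$end), j] <- TRUE
    }
  }
  out
}

#' Reconstruct monthly pumping schedules from demand and well histories
#'
#' Allocates each month's water-treatment-plant demand across the wells in
#' service that month in proportion to rated capacity:
#' `rate_i = demand * capacity_i / sum(capacity_j in service)`.  The rule is
#' the minimal allocation consistent with documented well capacities, service
#' dates and monthly totals; alternative policies can be passed as
#' `allocate`.
#'
#' @param wells List of [well_record()]s.
#' @param demand A [monthly_series] of WTP demand (m3/day, no missing
#'   months).
#' @param allocate Optional function `(demand_m, capacities) -> rates`
#'   replacing the capacity-proportional rule; must return rates summing to
#'   `demand_m`.
#' @return A [pumping_schedule()] covering the demand months exactly; total
#'   pumping equals demand every month.
#' @export
reconstruct_schedule <- function(wells, demand, allocate = NULL) {
  months <- series_months(demand)
  if (anyNA(demand$values))
    stop("reconstruct_schedule: demand series has missing months")
  svc <- service_matrix(wells, months)
  caps <- vapply(wells, function(w) w$capacity, 1.0)
  rates <- matrix(0, length(months), length(wells),
                  dimnames = dimnames(svc))
  for (i in seq_along(months)) {
    d <- demand$values[i]
    if (d == 0) next
    on <- svc[i, ]
    if (!any(on))
      stop("reconstruct_schedule: demand > 0 but no well in service in ",
           format(months[i]))
    cap_on <- sum(caps[on])
    if (d > cap_on)
      stop("reconstruct_schedule: capacity shortfall in ", format(months[i]),
           " (demand ", signif(d, 6), " m3/day > in-service capacity ",
           signif(cap_on, 6), " m3/day)")
    if (is.null(allocate)) {
      rates[i, on] <- d * caps[on] / cap_on
    } else {
      r <- allocate(d, caps[on])
      if (abs(sum(r) - d) > 1e-9 * max(d, 1))
        stop("reconstruct_schedule: allocate() rates do not sum to demand")
      rates[i, on] <- r
    }
  }
  pumping_schedule(months[1L], rates)
}
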