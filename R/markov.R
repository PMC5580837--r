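# Two-state Markov model of intermittent interconnection events between a
# contaminated and an uncontaminated distribution system.  States are
# monthly: "on" = at least one transfer event occurred that month, "off" =
# none.  Operational records are only partially documented; the chain is
# fitted to documented consecutive-month pairs and undocumented months are
# imputed by exact conditional (bridge) sampling given the documented
# neighbours within the same season.  Seasons (one per calendar year) are
# independent chains: transfers were driven by seasonal demand, an annually
# resetting condition, so there is no December-to-April memory.

#' Interconnection record table
#'
#' @param month `month_index` vector (or "YYYY-MM" stamps).
#' @param status Character: `documented_on`, `documented_off` or `unknown`.
#' @param hours Transfer hours within the month; required (and only allowed)
#'   for `documented_on` months, bounded by the hours in that calendar month.
#' @return data.frame of class `interconnection_records`.
#' @export
interconnection_records <- function(month, status, hours = NA_real_) {
  month <- as_month_index_like(month)
  status <- as.character(status)
  ok <- status %in% c("documented_on", "documented_off", "unknown")
  if (!all(ok)) stop("interconnection_records: bad status: ",
                     paste(unique(status[!ok]), collapse = ", "))
  hours <- rep_len(as.numeric(hours), length(status))
  if (any(!is.na(hours) & status != "documented_on"))
    stop("interconnection_records: hours only allowed for documented_on months")
  Hm <- hours_in_month(month)
  bad <- !is.na(hours) & (hours < 0 | hours > Hm)
  if (any(bad))
    stop("interconnection_records: hours outside [0, hours-in-month] in ",
         format(month[which(bad)[1L]]))
  structure(data.frame(month = format(month), status = status, hours = hours,
                       stringsAsFactors = FALSE),
            class = c("interconnection_records", "data.frame"))
}

#' Two-state Markov chain parameters
#'
#' @param p_stay_on P(on this month | on last month).
#' @param p_stay_off P(off this month | off last month).
#' @param initial_p_on P(on) for a month with no informative left neighbour.
#' @return A `two_state_chain` object.
#' @export
two_state_chain <- function(p_stay_on, p_stay_off, initial_p_on = 0.5) {
  p <- c(p_stay_on, p_stay_off, initial_p_on)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("two_state_chain: probabilities must lie in [0, 1]")
  structure(list(p_stay_on = p_stay_on, p_stay_off = p_stay_off,
                 initial_p_on = initial_p_on),
            class = "two_state_chain")
}

#' Fit the transfer chain to documented records
#'
#' Maximum-likelihood transition probabilities counted over documented
#' consecutive-month pairs (pairs spanning unknown months or season gaps are
#' excluded, since only adjacent calendar months are chain transitions).
#' `initial_p_on` is the documented on-fraction.
#'
#' @param records An [interconnection_records()] table.
#' @param pseudocount Added to every transition count (0 = pure ML; a small
#'   positive value regularises rows with few observed pairs).
#' @return A [two_state_chain()].
#' @export
fit_chain <- function(records, pseudocount = 0) {
  doc <- records[records$status != "unknown", , drop = FALSE]
  if (nrow(doc) == 0L) stop("fit_chain: no documented records")
  serial <- unclass(as_month_index(doc$month))
  o <- order(serial)
  serial <- serial[o]
  on <- doc$status[o] == "documented_on"
  consec <- which(diff(serial) == 1L)
  from_on <- on[consec]; to_on <- on[consec + 1L]
  n_oo <- sum(from_on & to_on); n_of <- sum(from_on & !to_on)
  n_fo <- sum(!from_on & to_on); n_ff <- sum(!from_on & !to_on)
  a <- pseudocount
  # a state that never appears in the documented record is inert: its row is
  # never exercised, so it defaults to stay-probability 1 rather than erroring
  p_stay_on <- if (n_oo + n_of + 2 * a > 0) {
    (n_oo + a) / (n_oo + n_of + 2 * a)
  } else if (!any(on)) 1 else
    stop("fit_chain: no documented on->* consecutive pairs; ",
         "supply a positive pseudocount or more records")
  p_stay_off <- if (n_ff + n_fo + 2 * a > 0) {
    (n_ff + a) / (n_ff + n_fo + 2 * a)
  } else if (all(on)) 1 else
    stop("fit_chain: no documented off->* consecutive pairs; ",
         "supply a positive pseudocount or more records")
  two_state_chain(p_stay_on = p_stay_on, p_stay_off = p_stay_off,
                  initial_p_on = mean(on))
}

#' Simulate interconnection events conditioned on documented records
#'
#' Monte Carlo imputation of the undocumented months: documented months are
#' fixed at their recorded status in every draw; each maximal undocumented
#' stretch is sampled from the chain *conditioned on both documented
#' neighbours* within its season (exact bridge sampling via backward
#' messages, equivalent to enumerating all compatible paths).  Seasons are
#' independent.  Documented record months outside `months_active` (e.g. a
#' continuous winter connection) are carried along as fixed columns.
#'
#' @param chain A [two_state_chain()].
#' @param years Integer vector of calendar years.
#' @param months_active Integer months (1--12) forming the transfer season,
#'   e.g. `4:8` for April--August.
#' @param records An [interconnection_records()] table (may be empty).
#' @param n_sims Number of draws, >= 1.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return An `event_summary`: list with `months` (`month_index`),
#'   `probability_on` (across-draw means), `draws` (n_sims x n_months 0/1
#'   matrix), `hours` (documented transfer hours per month, `NA` if
#'   undocumented), `expected_on_months` (named per year), `n_sims`, `seed`.
#' @export
simulate_events <- function(chain, years, months_active, records = NULL,
                            n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(chain, "two_state_chain"))
  if (length(years) == 0L || length(months_active) == 0L)
    stop("simulate_events: years and months_active must be non-empty")
  if (n_sims < 1L) stop("simulate_events: n_sims must be >= 1")
  months_active <- sort(unique(as.integer(months_active)))
  grid <- month_index(rep(years, each = length(months_active)),
                      rep(months_active, times = length(years)))
  rec_m <- if (!is.null(records) && nrow(records) > 0L)
    as_month_index(records$month) else new_month_index(integer(0))
  extra <- rec_m[month_year(rec_m) %in% years &
                   !(unclass(rec_m) %in% unclass(grid))]
  months <- new_month_index(sort(unique(c(unclass(grid), unclass(extra)))))
  nM <- length(months)
  status <- rep("unknown", nM)
  hours <- rep(NA_real_, nM)
  if (length(rec_m) > 0L) {
    pos <- match(unclass(rec_m), unclass(months))
    keep <- !is.na(pos)
    status[pos[keep]] <- records$status[keep]
    hours[pos[keep]] <- records$hours[keep]
  }
  draws <- matrix(0L, n_sims, nM)
  with_seed(seed, {
    yr <- month_year(months)
    for (y in unique(yr)) {
      cols <- which(yr == y)
      serial <- unclass(months[cols])
      seg_id <- cumsum(c(1L, diff(serial) != 1L))
      for (sg in unique(seg_id)) {
        sc <- cols[seg_id == sg]
        draws[, sc] <- sample_segment(chain, status[sc], n_sims)
      }
    }
  })
  prob <- colMeans(draws)
  exp_on <- vapply(split(prob, month_year(months)), sum, 1.0)
  structure(list(months = months, probability_on = prob, draws = draws,
                 hours = hours, expected_on_months = exp_on,
                 n_sims = n_sims, seed = seed),
            class = "event_summary")
}

# Exact conditional sampling of one contiguous run of months given partial
# observations.  Backward messages: beta_T(x) = e_T(x);
# beta_t(x) = e_t(x) * sum_x' P(x'|x) beta_{t+1}(x'); forward sampling from
# the normalised conditionals.  States: column 1 = off, column 2 = on.
sample_segment <- function(chain, status, n_sims) {
  Tn <- length(status)
  P <- rbind(c(chain$p_stay_off, 1 - chain$p_stay_off),   # from off
             c(1 - chain$p_stay_on, chain$p_stay_on))     # from on
  e <- matrix(1, Tn, 2L)
  e[status == "documented_on", 1L] <- 0
  e[status == "documented_off", 2L] <- 0
  beta <- matrix(0, Tn, 2L)
  beta[Tn, ] <- e[Tn, ]
  if (Tn > 1L) for (t in (Tn - 1L):1L)
    beta[t, ] <- e[t, ] * as.vector(P %*% beta[t + 1L, ])
  out <- matrix(0L, n_sims, Tn)
  p1 <- c(1 - chain$initial_p_on, chain$initial_p_on) * beta[1L, ]
  if (sum(p1) == 0) stop("simulate_events: documented records are impossible under the chain")
  x <- stats::rbinom(n_sims, 1L, p1[2L] / sum(p1))
  out[, 1L] <- x
  if (Tn > 1L) for (t in 2L:Tn) {
    # P(x_t = on | x_{t-1}, future evidence)
    w_on <- P[x + 1L, 2L] * beta[t, 2L]
    w_off <- P[x + 1L, 1L] * beta[t, 1L]
    tot <- w_on + w_off
    if (any(tot == 0)) stop("simulate_events: impossible documented sequence")
    x <- stats::rbinom(n_sims, 1L, w_on / tot)
    out[, t] <- x
  }
  out
}

#' Blend event simulations into a monthly concentration series
#'
#' Converts transfer-event draws into monthly mean concentrations for the
#' receiving system: in an "on" month the concentration is the duration-
#' weighted mixture `(h * on_conc + (H - h) * off_conc) / H` with `H` the
#' hours in the month and `h` the transfer hours (documented hours when
#' available, otherwise `event_hours`); in an "off" month it is `off_conc`.
#' The returned series is the across-draw mean, with `off_conc` filling
#' months between events.
#'
#' @param event An `event_summary` from [simulate_events()].
#' @param on_conc Concentration delivered during a transfer (ug/L): scalar
#'   or a [monthly_series] looked up per month.
#' @param off_conc Background concentration (ug/L): scalar or series.
#' @param event_hours Default transfer hours for an undocumented "on" month.
#' @return A [monthly_series] spanning the event months contiguously.
#' @export
blend_monthly <- function(event, on_conc, off_conc, event_hours) {
  months <- event$months
  full <- month_range(months[1L], months[length(months)])
  lookup <- function(x, m) {
    if (inherits(x, "monthly_series")) series_get(x, m) else rep(x, length(m))
  }
  on_v <- lookup(on_conc, full)
  off_v <- lookup(off_conc, full)
  if (any(is.na(off_v))) stop("blend_monthly: off_conc missing for some months")
  H <- hours_in_month(full)
  vals <- off_v
  pos <- match(unclass(months), unclass(full))
  for (k in seq_along(months)) {
    i <- pos[k]
    h <- if (!is.na(event$hours[k])) event$hours[k] else event_hours
    if (h > H[i]) stop("blend_monthly: event_hours ", h, " exceeds the ",
                       H[i], " hours of ", format(full[i]))
    p_on <- event$probability_on[k]
    if (p_on > 0 && is.na(on_v[i]))
      stop("blend_monthly: on_conc missing for ", format(full[i]))
    on_month_value <- (h * on_v[i] + (H[i] - h) * off_v[i]) / H[i]
    if (is.na(on_month_value)) on_month_value <- 0
    vals[i] <- p_on * on_month_value + (1 - p_on) * off_v[i]
  }
  monthly_series(full[1L], vals)
}
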