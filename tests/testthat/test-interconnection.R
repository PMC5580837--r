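season_months <- function(years, months = 4:8)
  month_index(rep(years, each = length(months)), rep(months, length(years)))

test_that("chain fitting counts documented consecutive pairs", {
  # On,On,Off,On,Off,Off within one season
  m <- season_months(1972, 4:9)
  st <- c("documented_on", "documented_on", "documented_off",
          "documented_on", "documented_off", "documented_off")
  hrs <- ifelse(st == "documented_on", 100, NA)
  ch <- fit_chain(interconnection_records(m, st, hrs))
  expect_equal(ch$p_stay_on, 1 / 3)     # On->On: 1 of 3
  expect_equal(ch$p_stay_off, 1 / 2)    # Off->Off: 1 of 2
  expect_equal(ch$initial_p_on, 0.5)

  # all documented on: degenerate chain
  m2 <- season_months(1972)
  ch2 <- fit_chain(interconnection_records(m2, rep("documented_on", 5), 100))
  expect_equal(ch2$p_stay_on, 1)

  # pairs spanning unknown months or season gaps are excluded
  m3 <- season_months(1972:1973)
  st3 <- rep("unknown", 10)
  st3[c(6, 7)] <- "documented_off"      # one Off->Off pair, nothing else
  ch3 <- fit_chain(interconnection_records(m3, st3))
  expect_equal(ch3$p_stay_off, 1)
  expect_equal(ch3$p_stay_on, 1)        # "on" never documented: inert row
  # a documented state whose row has zero pairs is an error without pseudocount
  st4 <- rep("unknown", 10); st4[c(1, 3)] <- "documented_on"
  expect_error(fit_chain(interconnection_records(m3, st4,
                                                 ifelse(st4 == "documented_on", 50, NA))),
               "pseudocount")
  ch4 <- fit_chain(interconnection_records(m3, st4,
                                           ifelse(st4 == "documented_on", 50, NA)),
                   pseudocount = 1)
  expect_equal(ch4$p_stay_on, 0.5)      # pure prior: (0+1)/(0+0+2)
})

test_that("masked synthetic histories are refit within tight bounds", {
  # 5,000 active months, half documented
  hist <- generate_interconnection_history(years = 1:1000,
                                           months_active = 4:8,
                                           p_on = 0.4, persistence = 0.6,
                                           frac_documented = 0.5, seed = 42L)
  expect_equal(length(hist$truth), 5000L)
  ch <- fit_chain(hist$records)
  expect_lt(abs(ch$p_stay_on - hist$chain$p_stay_on), 0.05)
  expect_lt(abs(ch$p_stay_off - hist$chain$p_stay_off), 0.05)
})

test_that("history generation is seeded, bounded and mask-invariant", {
  h1 <- generate_interconnection_history(1972:1985, 4:8, 0.35, 0.5, 0.5, 7L)
  h2 <- generate_interconnection_history(1972:1985, 4:8, 0.35, 0.5, 0.5, 7L)
  expect_identical(h1$truth, h2$truth)
  expect_identical(h1$records, h2$records)
  # masking never alters the truth: different documentation fractions, same truth
  h3 <- generate_interconnection_history(1972:1985, 4:8, 0.35, 0.5, 1.0, 7L)
  expect_identical(h1$truth, h3$truth)
  expect_false(any(h3$records$status == "unknown"))
  # degenerate chain: never on
  h4 <- generate_interconnection_history(1972:1985, 4:8, 0, 0.5, 0.5, 7L)
  expect_true(all(h4$truth == 0L))
  # long-run on fraction concentrates around p_on
  h5 <- generate_interconnection_history(1:2000, 4:8, 0.5, 0.5, 0, 13L)
  expect_lt(abs(mean(h5$truth) - 0.5), 0.02)
  expect_error(generate_interconnection_history(integer(0), 4:8, .5, .5, .5),
               "non-empty")
})

test_that("documented months are fixed in every simulation draw", {
  m <- season_months(1972)
  st <- c("documented_on", "unknown", "documented_off", "unknown",
          "documented_on")
  rec <- interconnection_records(m, st, ifelse(st == "documented_on", 120, NA))
  ch <- two_state_chain(0.7, 0.6, 0.4)
  ev <- simulate_events(ch, 1972, 4:8, rec, n_sims = 500L, seed = 5L)
  expect_equal(ev$probability_on[c(1L, 5L)], c(1, 1))
  expect_equal(ev$probability_on[3L], 0)
  expect_true(all(ev$draws[, 1L] == 1L))
  expect_true(all(ev$draws[, 3L] == 0L))
  # all documented: probabilities exactly 0/1 for any n_sims
  rec2 <- interconnection_records(m, rep("documented_off", 5))
  ev2 <- simulate_events(ch, 1972, 4:8, rec2, n_sims = 3L, seed = 1L)
  expect_equal(ev2$probability_on, rep(0, 5))
})

test_that("an unconstrained fair chain stays near one half", {
  ch <- two_state_chain(0.5, 0.5, 0.5)
  ev <- simulate_events(ch, 1:400, 4:8, records = NULL, n_sims = 5L,
                        seed = 3L)
  # 400 seasons x 5 months x 5 sims = 10,000 fair-coin months
  expect_lt(abs(mean(ev$draws) - 0.5), 0.03)
  expect_lt(abs(mean(ev$expected_on_months) - 2.5), 0.1)
  expect_equal(unname(ev$expected_on_months),
               unname(vapply(split(ev$probability_on, month_year(ev$months)),
                             sum, 1.0)))
})

test_that("bridge sampling matches exact path enumeration", {
  # single unknown month between two documented-on months
  m <- season_months(1975, 4:6)
  rec <- interconnection_records(m, c("documented_on", "unknown",
                                      "documented_on"), c(100, NA, 100))
  p_oo <- 0.9; p_ff <- 0.8
  ch <- two_state_chain(p_oo, p_ff, 0.5)
  exact <- p_oo^2 / (p_oo^2 + (1 - p_oo) * (1 - p_ff))   # two-path enumeration
  ev <- simulate_events(ch, 1975, 4:6, rec, n_sims = 20000L, seed = 9L)
  expect_gt(ev$probability_on[2L], 0.8)
  expect_lt(abs(ev$probability_on[2L] - exact), 0.01)

  # three unknown months between documented endpoints: enumerate 8 paths
  m2 <- season_months(1975, 4:8)
  rec2 <- interconnection_records(m2, c("documented_on", "unknown", "unknown",
                                        "unknown", "documented_off"),
                                  c(100, NA, NA, NA, NA))
  P <- rbind(c(p_ff, 1 - p_ff), c(1 - p_oo, p_oo))  # [from_off; from_on]
  paths <- as.matrix(expand.grid(x2 = 0:1, x3 = 0:1, x4 = 0:1))
  wts <- apply(paths, 1L, function(x) {
    states <- c(1L, x, 0L)
    prod(vapply(seq_len(4), function(t)
      P[states[t] + 1L, states[t + 1L] + 1L], 1.0))
  })
  marg <- vapply(1:3, function(k) sum(wts[paths[, k] == 1L]) / sum(wts), 1.0)
  ev2 <- simulate_events(ch, 1975, 4:8, rec2, n_sims = 20000L, seed = 10L)
  for (k in 1:3)
    expect_lt(abs(ev2$probability_on[k + 1L] - marg[k]), 0.015)
})

test_that("raising on-persistence never lowers an unknown month's probability", {
  m <- season_months(1980)
  rec <- interconnection_records(m, c("documented_on", "unknown", "unknown",
                                      "unknown", "documented_off"),
                                 c(90, NA, NA, NA, NA))
  probs <- vapply(c(0.3, 0.5, 0.7, 0.9), function(p) {
    ev <- simulate_events(two_state_chain(p, 0.6, 0.5), 1980, 4:8, rec,
                          n_sims = 4000L, seed = 77L)
    ev$probability_on[2L]
  }, 1.0)
  expect_true(all(diff(probs) > -0.02))
})

test_that("event blending mixes by transfer duration and probability", {
  m <- season_months(1978)
  rec_on <- interconnection_records(m, rep("documented_on", 5),
                                    hours_in_month(m))
  ch <- two_state_chain(0.9, 0.9, 0.5)
  ev_on <- simulate_events(ch, 1978, 4:8, rec_on, n_sims = 10L, seed = 1L)
  s_on <- blend_monthly(ev_on, on_conc = 66, off_conc = 2, event_hours = 240)
  expect_equal(s_on$values, rep(66, 5))   # fully connected months

  rec_off <- interconnection_records(m, rep("documented_off", 5))
  ev_off <- simulate_events(ch, 1978, 4:8, rec_off, n_sims = 10L, seed = 1L)
  s_off <- blend_monthly(ev_off, on_conc = 66, off_conc = 2, event_hours = 240)
  expect_equal(s_off$values, rep(2, 5))   # never connected

  # p = 0.5, h = H/2, on = 60, off = 0 -> expectation 15
  ev_half <- simulate_events(two_state_chain(0.5, 0.5, 0.5), 1:400, 4:8,
                             records = NULL, n_sims = 5L, seed = 21L)
  H <- hours_in_month(ev_half$months)
  s_half <- blend_monthly(ev_half, on_conc = 60, off_conc = 0,
                          event_hours = mean(H) / 2)
  active <- !is.na(match(unclass(series_months(s_half)),
                         unclass(ev_half$months)))
  expect_lt(abs(mean(s_half$values[active]) - 15), 1)

  # default hours only apply to undocumented months; over-long defaults error
  expect_error(blend_monthly(ev_half, 60, 0, event_hours = 800),
               "exceeds")
})
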