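test_that("steady flow reproduces the linear and parabolic 1-D profiles", {
  # Laplace: fixed heads 10 and 0 at the ends, no recharge -> linear profile
  site <- strip_site(ncol = 12L, h_left = 10, h_right = 0)
  hf <- solve_steady_flow(site)
  h <- hf$heads[[1L]][1L, 2L, ]
  L <- (12 - 1) * site$grid$dx
  x <- (seq_len(12) - 1) * site$grid$dx
  expect_lt(max(abs(h - (10 - 10 * x / L))), 1e-8)
  expect_lt(hf$budget$discrepancy, 1e-8)

  # uniform recharge between fixed heads: h(x) = h0 + (hL-h0) x/L + W x(L-x)/(2T)
  W <- 5e-4
  site2 <- strip_site(ncol = 21L, h_left = 8, h_right = 2, recharge = W)
  hf2 <- solve_steady_flow(site2)
  h2 <- hf2$heads[[1L]][1L, 2L, ]
  Tr <- 10 * 10   # kh * thickness
  L2 <- 20 * site2$grid$dx
  x2 <- (seq_len(21) - 1) * site2$grid$dx
  closed <- 8 + (2 - 8) * x2 / L2 + W * x2 * (L2 - x2) / (2 * Tr)
  expect_lt(max(abs(h2 - closed)) / max(abs(closed)), 0.01)
})

test_that("steady budgets close and the maximum principle holds", {
  for (seed in 1:4) {
    site <- with_seed(seed, {
      s <- strip_site(ncol = 10L, nrow = 6L,
                      h_left = runif(1, 5, 15), h_right = runif(1, 0, 4))
      s
    })
    hf <- solve_steady_flow(site)
    expect_lt(hf$budget$discrepancy, 0.005)
    # no recharge, no wells: interior heads bounded by boundary heads
    hb <- site$constant_head_cells$head
    expect_gte(min(hf$heads[[1L]]), min(hb) - 1e-9)
    expect_lte(max(hf$heads[[1L]]), max(hb) + 1e-9)
  }
  cfg <- generate_site("industrial-area", "small", 3L)
  hf <- solve_steady_flow(cfg$site)
  expect_lt(hf$budget$discrepancy, 0.005)
})

test_that("grid refinement converges at roughly second order", {
  # 1-D aquifer leaking to a fixed stage everywhere:
  # T h'' = La (h - stage), closed form in cosh/sinh between Dirichlet ends
  La <- 2e-3   # leakance 1/day
  stage <- 3; hL <- 9; hR <- 3
  mk <- function(ncol, dx) {
    st <- data.frame(layer = 1L, row = rep(1:3, each = ncol - 2L),
                     col = rep(2:(ncol - 1L), times = 3L),
                     stage = stage, conductance = La * dx * dx)
    strip_site(ncol = ncol, nrow = 3L, dx = dx, h_left = hL, h_right = hR,
               stream = st)
  }
  closed <- function(x, L) {
    k <- sqrt(La / (10 * 10))
    A <- (hR - stage - (hL - stage) * cosh(k * L)) / sinh(k * L)
    stage + (hL - stage) * cosh(k * x) + A * sinh(k * x)
  }
  err <- vapply(c(100, 50), function(dx) {
    ncol <- as.integer(1000 / dx) + 1L
    site <- mk(ncol, dx)
    h <- solve_steady_flow(site)$heads[[1L]][1L, 2L, ]
    x <- (seq_len(ncol) - 1) * dx
    max(abs(h - closed(x, 1000)))
  }, 1.0)
  expect_gt(err[1L] / err[2L], 3)
})

test_that("transient flow reduces to steady state with no forcing", {
  site <- strip_site(ncol = 12L, h_left = 10, h_right = 0,
                     wells = list(well_record("W", 2, 6, 1, capacity = 100)))
  steady <- solve_steady_flow(site)
  zero <- pumping_schedule(site$clock_start,
                           matrix(0, 12, 1, dimnames = list(NULL, "W")))
  tr <- solve_transient_flow(site, zero, steady, substeps_per_month = 2L)
  for (m in c(1L, 6L, 12L))
    expect_lt(max(abs(tr$heads[[m]] - steady$heads[[1L]])), 1e-8)
  expect_error(
    solve_transient_flow(site, pumping_schedule(month_index(1951, 2),
                                                matrix(0, 11, 1,
                                                       dimnames = list(NULL, "W"))),
                         steady),
    "does not cover")
})

test_that("transient drawdown matches the Theis solution", {
  n <- 81L; dx <- 50
  grid <- grid_spec(nlay = 1L, nrow = n, ncol = n, dx = dx, dy = dx,
                    layer_thickness = 10, layer_role = "aquifer")
  layers <- layer_properties(kh = 10, kv = 1, specific_storage = 2e-3,
                             porosity = 0.25)   # S = 0.02, T = 100 m2/day
  edges <- rbind(
    data.frame(layer = 1L, row = 1L, col = seq_len(n)),
    data.frame(layer = 1L, row = n, col = seq_len(n)),
    data.frame(layer = 1L, row = 2:(n - 1L), col = 1L),
    data.frame(layer = 1L, row = 2:(n - 1L), col = n))
  edges$head <- 0
  Q <- 500
  ctr <- (n + 1L) %/% 2L
  site <- site_model(grid, layers, constant_head_cells = edges,
                     wells = list(well_record("PW", ctr, ctr, 1, capacity = Q,
                                              service_intervals = list(
                                                c(month_index(1951, 1),
                                                  month_index(1951, 12))))),
                     clock_start = month_index(1951, 1),
                     clock_end = month_index(1951, 12))
  sched <- pumping_schedule(site$clock_start,
                            matrix(Q, 12, 1, dimnames = list(NULL, "PW")))
  steady <- solve_steady_flow(site)
  tr <- solve_transient_flow(site, sched, steady, substeps_per_month = 30L)
  S <- 2e-3 * 10; Tr <- 10 * 10
  t_end <- cumsum(days_in_month(site_clock(site)))
  for (mi in 1:3) {
    for (rcells in c(2L, 5L, 10L)) {     # radii 2dx .. 10dx
      robs <- rcells * dx
      u <- robs^2 * S / (4 * Tr * t_end[mi])
      s_theis <- Q / (4 * pi * Tr) * theis_W(u)
      s_num <- -tr$heads[[mi]][1L, ctr, ctr + rcells]
      expect_lt(abs(s_num - s_theis) / s_theis, 0.05)
    }
    expect_lt(tr$budget$discrepancy[mi], 0.005)
  }
})

test_that("time-step refinement changes late heads by under 0.1%", {
  cfg <- generate_site("industrial-area", "small", 5L)
  site <- cfg$site
  sched <- reconstruct_schedule(site$wells, cfg$demand)
  steady <- solve_steady_flow(site)
  t1 <- solve_transient_flow(site, sched, steady, substeps_per_month = 1L)
  t2 <- solve_transient_flow(site, sched, steady, substeps_per_month = 2L)
  last <- length(t1$heads)
  ref <- max(abs(t2$heads[[last]]))
  expect_lt(max(abs(t1$heads[[last]] - t2$heads[[last]])) / ref, 0.001)
})

test_that("cell flows satisfy continuity", {
  # uniform gradient: identical x-face flows, zero divergence
  site <- strip_site(ncol = 12L, nrow = 4L, h_left = 10, h_right = 0)
  hf <- solve_steady_flow(site)
  fl <- cell_flows(site, hf)
  per <- fl$periods[[1L]]
  expect_lt(diff(range(per$Qx)), 1e-8)
  expect_lt(max(abs(per$Qy)), 1e-8)

  # pumping cell: divergence equals the pumping rate
  Q <- 150
  site2 <- strip_site(ncol = 12L, nrow = 5L, h_left = 10, h_right = 0,
                      wells = list(well_record("W", 3, 6, 1, capacity = Q,
                                               service_intervals = list(
                                                 c(month_index(1951, 1),
                                                   month_index(1951, 12))))))
  sched <- pumping_schedule(site2$clock_start,
                            matrix(Q, 12, 1, dimnames = list(NULL, "W")))
  steady2 <- solve_steady_flow(site2)
  tr2 <- solve_transient_flow(site2, sched, steady2, substeps_per_month = 4L)
  fl2 <- cell_flows(site2, tr2, sched)
  per2 <- fl2$periods[[12L]]
  # net face inflow at the well cell ~ pumping rate at late time (near-steady)
  infl <- per2$Qx[1L, 3L, 5L] - per2$Qx[1L, 3L, 6L] +
    per2$Qy[1L, 2L, 6L] - per2$Qy[1L, 3L, 6L]
  expect_lt(abs(infl - Q) / Q, 0.005)

  # closed box with no sources: all flows vanish
  box <- closed_box_site()
  hb <- solve_steady_flow(box)
  flb <- cell_flows(box, hb)
  expect_lt(max(abs(flb$periods[[1L]]$Qx)), 1e-10)
  expect_lt(max(abs(flb$periods[[1L]]$Qy)), 1e-10)
  expect_lt(max(flb$periods[[1L]]$ext_in), 1e-10)
})

test_that("residual reports match their definition", {
  site <- strip_site(ncol = 12L, h_left = 10, h_right = 0)
  hf <- solve_steady_flow(site)
  obs <- data.frame(layer = 1L, row = 2L, col = c(3L, 5L, 8L),
                    month = "1951-03")
  obs$head <- vapply(obs$col, function(cc) hf$heads[[1L]][1L, 2L, cc], 1.0)
  rep0 <- compute_residuals(list(head_obs = obs), hf)
  expect_equal(rep0$residual, rep(0, 3))
  expect_equal(attr(rep0, "fraction_within"), 1)

  # noisy observations: fraction within +/-1.5 m at sd 0.5 ~ Phi(3)-Phi(-3)
  n <- 200L
  obs2 <- obs[rep(1:3, length.out = n), ]
  noise <- with_seed(99L, rnorm(n, 0, 0.5))
  obs2$head <- obs2$head + noise
  rep2 <- compute_residuals(list(head_obs = obs2), hf)
  p <- pnorm(3) - pnorm(-3)
  lo <- qbinom(0.005, n, p) / n
  expect_gte(attr(rep2, "fraction_within"), lo)
  expect_error(compute_residuals(list(head_obs = obs[0, ]), hf), "no usable")
})
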