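single_pipe_net <- function(demand = 500, length = 800, diameter = 0.3,
                            C = 120, head = 50) {
  pipe_network(
    nodes = data.frame(id = c("res", "J"), elev = c(0, 5),
                       demand = c(0, demand), area = c("boundary", "town"),
                       type = c("reservoir", "junction"),
                       head = c(head, NA)),
    links = data.frame(id = "p1", from = "res", to = "J", type = "pipe",
                       length = length, diameter = diameter, roughness = C,
                       h0 = NA, r = NA, status = "open"))
}

hw_loss <- function(Q_m3day, L, D, C) {
  10.667 * L * (Q_m3day / 86400)^1.852 / (C^1.852 * D^4.871)
}

test_that("a single pipe carries the demand with Hazen-Williams loss", {
  net <- single_pipe_net()
  sol <- solve_hydraulics(net, hour = 1L)
  expect_equal(unname(sol$flows[["p1"]]), 500, tolerance = 1e-9)
  expect_equal(unname(sol$heads[["res"]] - sol$heads[["J"]]),
               hw_loss(500, 800, 0.3, 120), tolerance = 1e-6)
})

test_that("a symmetric loop splits flow evenly and zero demand is quiescent", {
  nodes <- data.frame(id = c("res", "A", "B"), elev = 0,
                      demand = c(0, 0, 600),
                      area = c("boundary", "mid", "end"),
                      type = c("reservoir", "junction", "junction"),
                      head = c(40, NA, NA))
  links <- data.frame(id = c("up", "L1", "L2"),
                      from = c("res", "A", "A"), to = c("A", "B", "B"),
                      type = "pipe", length = c(200, 500, 500),
                      diameter = c(0.4, 0.25, 0.25), roughness = 120,
                      h0 = NA, r = NA, status = "open")
  net <- pipe_network(nodes, links)
  sol <- solve_hydraulics(net)
  expect_equal(unname(sol$flows[["L1"]]), unname(sol$flows[["L2"]]),
               tolerance = 1e-9)
  expect_equal(unname(sol$flows[["up"]]), 600, tolerance = 1e-9)

  net0 <- pipe_network(transform(nodes, demand = 0), links)
  sol0 <- solve_hydraulics(net0)
  expect_lt(max(abs(sol0$flows)), 1e-6)
  expect_lt(diff(range(sol0$heads)), 1e-6)
})

test_that("hydraulics are invariant to node relabelling", {
  cfg <- generate_site("two-system", "small", 7L)
  net <- pipe_network_from_list(cfg$network)
  lk <- net$links; lk$status[lk$type == "pump"] <- "open"
  net_open <- pipe_network(net$nodes, lk, net$patterns)
  sol1 <- solve_hydraulics(net_open)
  perm <- with_seed(5L, sample(nrow(net$nodes)))
  net2 <- pipe_network(net$nodes[perm, ], lk, net$patterns)
  sol2 <- solve_hydraulics(net2)
  expect_equal(sol1$flows[names(sol1$flows)], sol2$flows[names(sol1$flows)],
               tolerance = 1e-6)
})

test_that("closed valves that strand demand raise a connectivity error", {
  nodes <- data.frame(id = c("res", "A"), elev = 0, demand = c(0, 100),
                      area = c("boundary", "x"),
                      type = c("reservoir", "junction"), head = c(30, NA))
  links <- data.frame(id = "v", from = "res", to = "A", type = "valve",
                      length = NA, diameter = NA, roughness = NA,
                      h0 = NA, r = NA, status = "closed")
  net <- pipe_network(nodes, links)
  expect_error(solve_hydraulics(net), "disconnected")
})

test_that("plug flow delays arrival by one travel time", {
  net <- single_pipe_net(demand = 600, length = 1000, diameter = 0.3)
  sol <- solve_hydraulics(net)
  vol <- pi * 0.15^2 * 1000                       # pipe volume, m3
  tau <- vol / (600 / 24)                         # travel time, hours
  eps <- simulate_quality(net, list(sol), source_conc = 80,
                          duration = ceiling(2 * tau), step = 1)
  conc <- eps$node_conc[, "J"]
  expect_lt(max(conc[eps$times < tau - 1]), 1e-9)
  expect_equal(unname(conc[which(eps$times >= tau + 1)[1L]]), 80,
               tolerance = 1e-6)
  # mass balance over the run
  m <- eps$mass
  expect_lt(abs(m$inflow - m$delivered - m$stored) / m$inflow, 0.005)

  # a step much coarser than the shortest travel time warns about accuracy
  short <- single_pipe_net(demand = 600, length = 50, diameter = 0.3)
  ssol <- solve_hydraulics(short)
  expect_warning(simulate_quality(short, list(ssol), 80, duration = 4,
                                  step = 4), "coarse")
})

test_that("junction mixing follows the flow-weighted mean", {
  # two inflows (Q = 2q at 30 ug/L, q clean) meeting at a junction -> 20
  nodes <- data.frame(id = c("res", "B", "X"), elev = 0,
                      demand = c(0, 0, 900),
                      area = c("boundary", "b", "x"),
                      type = c("reservoir", "junction", "junction"),
                      head = c(30, NA, NA))
  links <- data.frame(id = c("hot", "cold"), from = c("res", "B"),
                      to = c("X", "X"), type = "pipe",
                      length = c(50, 5000), diameter = c(0.3, 0.6),
                      roughness = 120, h0 = NA, r = NA, status = "open")
  net <- pipe_network(nodes, links)
  hyd <- list(flows = c(hot = 600, cold = 300), heads = c(res = 30, B = 29, X = 28),
              demands = c(res = 0, B = 0, X = 900), iterations = 1L)
  eps <- simulate_quality(net, list(hyd), source_conc = 30, duration = 24,
                          step = 1)
  # "cold" leg is long enough to stay clean for the whole day
  expect_equal(unname(eps$node_conc[24, "X"]), 20, tolerance = 1e-6)
})

test_that("area means are demand-weighted over nodes and steps", {
  nodes <- data.frame(id = c("res", "A", "B"), elev = 0, demand = c(0, 1, 3),
                      area = c("boundary", "town", "town"),
                      type = c("reservoir", "junction", "junction"),
                      head = c(30, NA, NA))
  links <- data.frame(id = c("p1", "p2"), from = c("res", "A"),
                      to = c("A", "B"), type = "pipe", length = 100,
                      diameter = 0.3, roughness = 120, h0 = NA, r = NA,
                      status = "open")
  net <- pipe_network(nodes, links)
  fake <- structure(list(times = c(1, 2),
                         node_conc = rbind(c(res = 0, A = 40, B = 0),
                                           c(res = 0, A = 40, B = 0)),
                         flows = NULL, step = 1, net = net),
                    class = "eps_result")
  expect_equal(area_mean(fake, "town"), 10)        # (1*40 + 3*0) / 4
  fake$node_conc[] <- 7
  expect_equal(area_mean(fake, "town"), 7)
  expect_error(area_mean(fake, "suburb"), "town")
})

test_that("event scenarios saturate with duration and order areas by distance", {
  cfg <- generate_site("two-system", "small", 7L)
  net <- pipe_network_from_list(cfg$network)
  z <- run_event_scenario(net, list(type = "pump"), source_conc = 50,
                          duration = 0)
  expect_true(all(z$area_means == 0))
  sc <- run_event_scenario(net, list(type = "pump"), source_conc = 50,
                           duration = 240, step = 1)
  expect_gte(sc$area_means[["near"]], sc$area_means[["distal"]])
  expect_lte(max(sc$result$node_conc), 50 + 1e-9)
  # long event >> travel time: every area approaches the source concentration
  # (the coarse 2 h step legitimately triggers the accuracy warning)
  lng <- suppressWarnings(
    run_event_scenario(net, list(type = "valve"), source_conc = 50,
                       duration = 1200, step = 2))
  expect_true(all(abs(lng$area_means - 50) / 50 < 0.01))
  # halving the reporting step moves area means by well under 1%
  sc2 <- run_event_scenario(net, list(type = "pump"), source_conc = 50,
                            duration = 240, step = 0.5)
  expect_lt(max(abs(sc2$area_means - sc$area_means)) / 50, 0.01)
})

test_that("the INP dialect reader matches the native description", {
  inp <- c(
    "[TITLE]", "two-branch test net",
    "[RESERVOIRS]", "res 45.0",
    "[JUNCTIONS]", "; id elev demand area", "A 5.0 300 near", "B 8.0 0 far",
    "[PIPES]", "p1 res A 400 0.3 120", "p2 A B 600 0.2 110",
    "[PUMPS]", "bp res A 40 1e-6",
    "[VALVES]", "v1 res A",
    "[STATUS]", "bp open", "v1 closed",
    "[DEMANDS]", "B 150",
    "[PATTERNS]", "default 1 1 1 1 1 1 1 1 1 1 1 1",
    "default 1 1 1 1 1 1 1 1 1 1 1 1")
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(inp, f)
  net <- read_inp(f)
  expect_s3_class(net, "pipe_network")
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(net$nodes$demand[net$nodes$id == "B"], 150)
  expect_equal(net$links$status[net$links$id == "v1"], "closed")
  expect_equal(length(net$patterns$default), 24L)
  sol <- solve_hydraulics(net)
  expect_equal(unname(sol$flows[["p1"]] + sol$flows[["bp"]]), 450,
               tolerance = 1e-6)

  writeLines(c(inp, "[OPTIONS]", "units SI"), f)
  expect_error(read_inp(f), "OPTIONS")
})
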