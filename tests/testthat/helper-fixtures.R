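# Small programmatic fixtures shared across test files.

# 1-layer homogeneous strip: Dirichlet heads at the two end columns.
strip_site <- function(ncol = 12L, nrow = 3L, dx = 100, kh = 10, thick = 10,
                       h_left = 10, h_right = 0, recharge = 0,
                       porosity = 0.25, ss = 1e-5, stream = NULL,
                       sources = list(), wells = list(),
                       clock_start = month_index(1951, 1), months = 12L) {
  grid <- grid_spec(nlay = 1L, nrow = nrow, ncol = ncol, dx = dx, dy = dx,
                    layer_thickness = thick, layer_role = "aquifer")
  layers <- layer_properties(kh = kh, kv = kh / 10,
                             specific_storage = ss, porosity = porosity)
  ch <- rbind(
    data.frame(layer = 1L, row = seq_len(nrow), col = 1L, head = h_left),
    data.frame(layer = 1L, row = seq_len(nrow), col = ncol, head = h_right))
  site_model(grid = grid, layers = layers, constant_head_cells = ch,
             stream_cells = stream, recharge = recharge,
             sources = sources, wells = wells,
             clock_start = clock_start,
             clock_end = month_add(clock_start, months - 1L))
}

# closed box: a single anchoring constant-head cell, no recharge -> no flow
closed_box_site <- function(n = 6L, nlay = 1L) {
  grid <- grid_spec(nlay = nlay, nrow = n, ncol = n, dx = 50, dy = 50,
                    layer_thickness = rep(10, nlay),
                    layer_role = rep("aquifer", nlay))
  layers <- layer_properties(kh = rep(5, nlay), kv = rep(0.5, nlay),
                             specific_storage = rep(1e-5, nlay),
                             porosity = rep(0.3, nlay))
  site_model(grid = grid, layers = layers,
             constant_head_cells = data.frame(layer = 1L, row = 1L, col = 1L,
                                              head = 5),
             recharge = 0, clock_start = month_index(1951, 1),
             clock_end = month_index(1951, 12))
}

# constant schedule helper
flat_demand <- function(site, value) {
  clock <- site_clock(site)
  monthly_series(clock[1L], rep(value, length(clock)), units = "m3/day")
}

# Theis well function W(u) by numerical integration of exp(-x)/x
theis_W <- function(u) {
  vapply(u, function(ui)
    stats::integrate(function(x) exp(-x) / x, ui, Inf,
                     rel.tol = 1e-10)$value, 1.0)
}

# Ogata-Banks solution for a continuous inlet at C0 into a semi-infinite
# 1-D column: C/C0 = 0.5 [erfc((x-vt)/(2 sqrt(Dt))) +
#                         exp(vx/D) erfc((x+vt)/(2 sqrt(Dt)))]
ogata_banks <- function(x, t, v, D, C0 = 1) {
  erfc <- function(z) 2 * stats::pnorm(-sqrt(2) * z)
  a <- erfc((x - v * t) / (2 * sqrt(D * t)))
  # guard the overflow-prone product: exp(vx/D) * erfc(large) -> ~0
  z2 <- (x + v * t) / (2 * sqrt(D * t))
  b <- ifelse(z2 > 25, 0, exp(pmin(v * x / D, 700)) * erfc(z2))
  C0 * 0.5 * (a + b)
}

# tiny two-well record set used across well/mixing tests
two_wells <- function(clock_start = month_index(1951, 1),
                      clock_end = month_index(1951, 12)) {
  list(
    well_record("A", row = 1L, col = 2L, screened_layers = 1L, capacity = 100,
                service_intervals = list(c(clock_start, clock_end))),
    well_record("B", row = 1L, col = 3L, screened_layers = 1L, capacity = 300,
                service_intervals = list(c(clock_start, clock_end))))
}
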