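test_that("unit conversions reproduce the documented values exactly", {
  expect_equal(convert_units(0.9e6, "gal", "m3"), 3406.8706056)
  expect_equal(convert_units(0.9e6, "gal", "m3", sig_figs = 2), 3400)
  expect_equal(convert_units(1.6e6, "gal", "m3", sig_figs = 2), 6100)
  expect_equal(convert_units(70, "mi", "km"), 112.65408)
  expect_equal(convert_units(70, "mi", "km", sig_figs = 3), 113)
  expect_equal(convert_units(1, "ft", "m"), 0.3048)
  expect_equal(convert_units(0, "gal", "m3"), 0)
  expect_equal(convert_units(0, "Mgal/day", "m3/day"), 0)
})

test_that("unit conversions round-trip and reject unknown pairs", {
  pairs <- list(c("ft", "m"), c("mi", "km"), c("gal", "m3"),
                c("Mgal/day", "m3/day"))
  for (p in pairs) {
    x <- c(0.37, 1, 941.5)
    back <- convert_units(convert_units(x, p[1], p[2]), p[2], p[1])
    expect_equal(back, x, tolerance = 1e-12)
    back2 <- convert_units(convert_units(x, p[2], p[1]), p[1], p[2])
    expect_equal(back2, x, tolerance = 1e-12)
  }
  expect_error(convert_units(1, "ft", "km"), "unsupported unit pair")
  expect_error(convert_units(1, "acre", "m2"), "unsupported unit pair")
})

test_that("month arithmetic follows the calendar", {
  expect_equal(format(month_range(month_index(1972, 6), month_index(1972, 8))),
               c("1972-06", "1972-07", "1972-08"))
  expect_equal(length(month_range(month_index(1984, 12), month_index(1985, 1))), 2L)
  expect_equal(format(month_range(month_index(1951, 1), month_index(1951, 1))),
               "1951-01")
  expect_error(month_range(month_index(1952, 1), month_index(1951, 1)),
               "after end")
  expect_equal(month_diff(month_index(1985, 2), month_index(1972, 7)), 151L)
  expect_equal(days_in_month(month_index(1984, 2)), 29L)  # leap year
  expect_equal(days_in_month(month_index(1900, 2)), 28L)  # century rule
  expect_equal(hours_in_month(month_index(1985, 1)), 744L)
  m <- month_index(1957, 11)
  expect_identical(unclass(as_month_index(format(m))), unclass(m))
  expect_error(month_index(1951, 13), "1..12")
})

test_that("monthly series enforce non-negativity and explicit missingness", {
  s <- monthly_series(month_index(1951, 1), c(1, NA, 3))
  expect_equal(length(s), 3L)
  expect_equal(series_get(s, month_index(1951, 2)), NA_real_)
  expect_equal(series_get(s, month_index(1951, 3)), 3)
  expect_equal(series_get(s, month_index(1960, 1)), NA_real_)
  expect_error(monthly_series(month_index(1951, 1), c(1, -2)), "negative")
  w <- series_window(s, month_index(1951, 2), month_index(1951, 3))
  expect_equal(w$values, c(NA, 3))
  expect_equal(format(series_months(w)[1L]), "1951-02")
  pk <- series_peak(s)
  expect_equal(pk$value, 3)
  expect_equal(format(pk$month), "1951-03")
})

test_that("domain type invariants are enforced at construction", {
  expect_error(contaminant_spec("X", retardation = 0.5), "retardation")
  expect_error(contaminant_spec("X", disp_long = 1, disp_transv = 2),
               "disp_transv")
  expect_error(contaminant_spec("X", mcl = 0), "mcl")
  expect_error(grid_spec(nlay = 2, nrow = 4, ncol = 4, dx = 0, dy = 10,
                         layer_thickness = c(1, 1)), "dx")
  expect_error(grid_spec(nlay = 2, nrow = 4, ncol = 4, dx = 10, dy = 10,
                         layer_thickness = c(1, -1)), "layer_thickness")
  expect_error(grid_spec(nlay = 1, nrow = 4, ncol = 4, dx = 10, dy = 10,
                         layer_thickness = 1, layer_role = "swamp"),
               "layer_role")
  expect_error(layer_properties(kh = 1, kv = 1, specific_storage = 1e-5,
                                porosity = 1.2), "porosity")
  expect_error(source_term(cbind(1, 1, 1), concentration = -5,
                           start = month_index(1951, 1),
                           end = month_index(1952, 1)), "concentration")
  expect_error(source_term(cbind(1, 1, 1), concentration = 5,
                           start = month_index(1953, 1),
                           end = month_index(1952, 1)), "after end")
  expect_error(well_record("W", 1, 1, screened_layers = 1, capacity = -1),
               "capacity")
  expect_error(well_record("W", 1, 1, screened_layers = 1, capacity = 10,
                           service_intervals = list(
                             c(month_index(1951, 1), month_index(1952, 6)),
                             c(month_index(1952, 1), month_index(1953, 1)))),
               "overlapping")
})

test_that("site model validation catches structural errors", {
  site <- strip_site()
  expect_s3_class(site, "site_model")
  # well outside grid names the well
  expect_error(
    strip_site(wells = list(well_record("W-999", row = 99, col = 2,
                                        screened_layers = 1, capacity = 10))),
    "W-999")
  # well screened in an aquitard layer
  grid2 <- grid_spec(nlay = 2, nrow = 3, ncol = 6, dx = 100, dy = 100,
                     layer_thickness = c(10, 5),
                     layer_role = c("aquifer", "aquitard"))
  lay2 <- layer_properties(kh = c(10, 0.01), kv = c(1, 0.001),
                           specific_storage = c(1e-5, 1e-4),
                           porosity = c(0.25, 0.35))
  expect_error(
    site_model(grid2, lay2,
               constant_head_cells = data.frame(layer = 1, row = 1, col = 1,
                                                head = 5),
               wells = list(well_record("W", 2, 2, screened_layers = 2,
                                        capacity = 10)),
               clock_start = month_index(1951, 1),
               clock_end = month_index(1951, 12)),
    "non-aquifer")
  # no head control
  expect_error(
    site_model(grid2, lay2, clock_start = month_index(1951, 1),
               clock_end = month_index(1951, 12)),
    "constant-head or stream")
  # clock too short
  expect_error(
    site_model(grid2, lay2,
               constant_head_cells = data.frame(layer = 1, row = 1, col = 1,
                                                head = 5),
               clock_start = month_index(1951, 1),
               clock_end = month_index(1951, 6)),
    "12 months")
})

test_that("config files load, convert units and round-trip", {
  si_yaml <- '
schema: 1
units: si
grid: {nlay: 1, nrow: 4, ncol: 6, dx: 30.48, dy: 30.48,
       layer_thickness: [3.048], layer_role: [aquifer]}
layers:
  - {kh: 3.048, kv: 0.3048, specific_storage: 3.2808398950131233e-05, porosity: 0.25}
boundaries:
  constant_head:
    - {layer: 1, row: 1, col: 1, head: 3.048}
recharge: 0.0003048
sources: []
wells:
  - {id: SW-1, row: 2, col: 3, screened_layers: [1], capacity: 3785.411784,
     service: [["1951-01", "1951-12"]]}
clock: {start: "1951-01", end: "1951-12"}
demand: {constant: 378.5411784}
contaminants:
  - {name: TCE, retardation: 1.2, decay_rate: 0.0, disp_long: 3.048,
     disp_transv: 0.3048, mol_diffusion: 0, mcl: 5}
'
  us_yaml <- '
schema: 1
units: us
grid: {nlay: 1, nrow: 4, ncol: 6, dx: 100, dy: 100,
       layer_thickness: [10], layer_role: [aquifer]}
layers:
  - {kh: 10, kv: 1, specific_storage: 1.0e-05, porosity: 0.25}
boundaries:
  constant_head:
    - {layer: 1, row: 1, col: 1, head: 10}
recharge: 0.001
sources: []
wells:
  - {id: SW-1, row: 2, col: 3, screened_layers: [1], capacity: 1,
     service: [["1951-01", "1951-12"]]}
clock: {start: "1951-01", end: "1951-12"}
demand: {constant: 0.1}
contaminants:
  - {name: TCE, retardation: 1.2, decay_rate: 0.0, disp_long: 10,
     disp_transv: 1, mol_diffusion: 0, mcl: 5}
'
  f_si <- withr::local_tempfile(fileext = ".yaml")
  f_us <- withr::local_tempfile(fileext = ".yaml")
  writeLines(si_yaml, f_si); writeLines(us_yaml, f_us)
  cfg_si <- load_config(f_si)
  cfg_us <- load_config(f_us)
  expect_equal(config_to_list(cfg_si), config_to_list(cfg_us),
               tolerance = 1e-12)
  expect_equal(cfg_us$site$grid$dx, 30.48)
  expect_equal(cfg_us$demand$values[1L], 378.5411784)

  # serialize -> parse is idempotent
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg_si, f2)
  cfg2 <- load_config(f2)
  f3 <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg2, f3)
  expect_identical(config_to_list(cfg2), config_to_list(load_config(f3)))

  # schema violations name the problem
  bad <- sub('row: 2, col: 3', 'row: 99, col: 3', si_yaml)
  fb <- withr::local_tempfile(fileext = ".yaml")
  writeLines(bad, fb)
  expect_error(load_config(fb), "SW-1|outside")
  expect_error(load_config(tempfile()), "no such file")
  bad2 <- sub("schema: 1", "schema: 99", si_yaml)
  writeLines(bad2, fb)
  expect_error(load_config(fb), "schema")
})
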