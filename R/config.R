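#' Read a site configuration file
#'
#' Reads, validates and unit-normalises a YAML site description into a
#' [site_model()] plus run settings.  The schema (versioned `schema: 1`) is:
#'
#' ```yaml
#' schema: 1
#' units: si            # "si" or "us"
#' grid: {nlay, nrow, ncol, dx, dy, layer_thickness: [...], layer_role: [...]}
#' layers: [{kh, kv, specific_storage, porosity}, ...]   # one per layer, top first
#' boundaries:
#'   constant_head: [{layer, row, col, head}, ...]
#'   streams: [{layer, row, col, stage, conductance}, ...]
#' recharge: 0.0003     # scalar, applied to layer 1
#' sources: [{cells: [[layer,row,col], ...], concentration, start, end}, ...]
#' wells: [{id, row, col, screened_layers: [...], capacity, service: [[start, end], ...]}, ...]
#' clock: {start: "1951-01", end: "1962-12"}
#' demand: {constant: 2000.0}          # or {start: "1951-01", values: [...]}
#' contaminants: [{name, retardation, decay_rate, disp_long, disp_transv,
#'                 mol_diffusion, mcl}, ...]
#' settings: {substeps_per_month: 1, ...}       # free-form run settings
#' interconnection: {...}                       # optional, two-system sites
#' ```
#'
#' Grid indices are 1-based with layer 1 at the top.  Months are ISO stamps
#' `"YYYY-MM"`.  Concentrations are ug/L in both unit systems.  Under
#' `units: us`, lengths (dx, dy, thicknesses, heads, stages, dispersivities)
#' are in ft, conductivities in ft/day, specific storage in 1/ft, stream
#' conductance in ft2/day, recharge in ft/day, and pumping capacity/demand in
#' Mgal/day; everything is converted to SI (m, day, m3/day) on load.
#'
#' @param path Path to the YAML file.
#' @return A list of class `site_config` with elements `site` (a
#'   [site_model()] in SI units), `demand` (a [monthly_series] of m3/day over
#'   the clock, or `NULL`), `contaminants` (named list of
#'   [contaminant_spec()]), `settings` (list), `interconnection` (list or
#'   `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  parse_config(raw)
}

#' @rdname load_config
#' @param raw A list with the structure of the YAML document (as returned by
#'   `yaml::read_yaml`); used directly by the generators and the uncertainty
#'   engine, which perturb configurations in memory.
#' @export
parse_config <- function(raw) {
  if (is.null(raw$schema) || raw$schema != 1)
    stop("config: missing or unsupported 'schema' (expected 1)")
  units <- raw$units %||% "si"
  if (!units %in% c("si", "us")) stop("config: units must be 'si' or 'us'")
  len <- function(x) if (units == "us") convert_units(x, "ft", "m") else x
  inv_len <- function(x) if (units == "us") x / 0.3048 else x  # 1/ft -> 1/m
  rate <- function(x) if (units == "us") convert_units(x, "Mgal/day", "m3/day") else x
  area_rate <- function(x) if (units == "us") x * 0.3048^2 else x  # ft2/day

  g <- raw$grid
  if (is.null(g)) stop("config: missing 'grid'")
  grid <- grid_spec(nlay = g$nlay, nrow = g$nrow, ncol = g$ncol,
                    dx = len(g$dx), dy = len(g$dy),
                    layer_thickness = len(unlist(g$layer_thickness)),
                    layer_role = unlist(g$layer_role))
  lay <- raw$layers
  if (is.null(lay) || length(lay) != grid$nlay)
    stop("config: 'layers' must list one property set per grid layer")
  layers <- layer_properties(
    kh = len(vapply(lay, function(l) as.numeric(l$kh), 1.0)),
    kv = len(vapply(lay, function(l) as.numeric(l$kv), 1.0)),
    specific_storage = inv_len(vapply(lay, function(l) as.numeric(l$specific_storage), 1.0)),
    porosity = vapply(lay, function(l) as.numeric(l$porosity), 1.0))

  bdf <- function(recs, extra) {
    if (is.null(recs) || length(recs) == 0L) return(NULL)
    do.call(rbind, lapply(recs, function(r) as.data.frame(r[c("layer", "row", "col", extra)])))
  }
  ch <- bdf(raw$boundaries$constant_head, "head")
  if (!is.null(ch)) ch$head <- len(ch$head)
  st <- bdf(raw$boundaries$streams, c("stage", "conductance"))
  if (!is.null(st)) { st$stage <- len(st$stage); st$conductance <- area_rate(st$conductance) }

  sources <- lapply(raw$sources %||% list(), function(s) {
    cells <- do.call(rbind, lapply(s$cells, as.integer))
    source_term(cells, s$concentration, as_month_index(s$start), as_month_index(s$end))
  })
  wells <- lapply(raw$wells %||% list(), function(w) {
    well_record(id = w$id, row = w$row, col = w$col,
                screened_layers = unlist(w$screened_layers),
                capacity = rate(w$capacity),
                service_intervals = lapply(w$service %||% list(), function(p)
                  list(as_month_index(p[[1L]]), as_month_index(p[[2L]]))))
  })
  if (is.null(raw$clock)) stop("config: missing 'clock'")
  site <- site_model(grid = grid, layers = layers,
                     constant_head_cells = ch, stream_cells = st,
                     recharge = len(raw$recharge %||% 0),
                     sources = sources, wells = wells,
                     clock_start = as_month_index(raw$clock$start),
                     clock_end = as_month_index(raw$clock$end))

  demand <- NULL
  if (!is.null(raw$demand)) {
    clock <- site_clock(site)
    if (!is.null(raw$demand$constant)) {
      demand <- monthly_series(clock[1L],
                               rep(rate(raw$demand$constant), length(clock)),
                               units = "m3/day")
    } else {
      demand <- monthly_series(as_month_index(raw$demand$start),
                               rate(unlist(raw$demand$values)), units = "m3/day")
    }
  }
  contaminants <- lapply(raw$contaminants %||% list(), function(cc)
    contaminant_spec(name = cc$name, retardation = cc$retardation %||% 1,
                     decay_rate = cc$decay_rate %||% 0,
                     disp_long = len(cc$disp_long %||% 10),
                     disp_transv = len(cc$disp_transv %||% 1),
                     mol_diffusion = cc$mol_diffusion %||% 0,
                     mcl = cc$mcl %||% 5))
  names(contaminants) <- vapply(contaminants, function(cc) cc$name, "")

  structure(list(site = site, demand = demand, contaminants = contaminants,
                 settings = raw$settings %||% list(),
                 interconnection = raw$interconnection,
                 network = raw$network),
            class = "site_config")
}

#' Write a site configuration to YAML
#'
#' Serialises a configuration (always in SI units, `units: si`) so that
#' `load_config(write_config(cfg, path))` round-trips to an equal model.
#'
#' @param config A `site_config` (from [load_config()] or the generators).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
config_to_list <- function(config) {
  site <- config$site
  g <- site$grid
  rows_of <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  raw <- list(
    schema = 1L, units = "si",
    grid = list(nlay = g$nlay, nrow = g$nrow, ncol = g$ncol, dx = g$dx, dy = g$dy,
                layer_thickness = g$layer_thickness, layer_role = g$layer_role),
    layers = rows_of(as.data.frame(site$layers)),
    boundaries = list(constant_head = rows_of(site$constant_head_cells),
                      streams = rows_of(site$stream_cells)),
    recharge = site$recharge[1L, 1L],
    sources = lapply(site$sources, function(s) list(
      cells = lapply(seq_len(nrow(s$cells)), function(i) as.integer(s$cells[i, ])),
      concentration = s$concentration,
      start = format(s$start), end = format(s$end))),
    wells = lapply(site$wells, function(w) list(
      id = w$id, row = w$row, col = w$col,
      screened_layers = w$screened_layers, capacity = w$capacity,
      service = lapply(w$service_intervals, function(p)
        list(format(p$start), format(p$end))))),
    clock = list(start = format(site$clock_start), end = format(site$clock_end))
  )
  if (!all(site$recharge == site$recharge[1L, 1L]))
    stop("write_config: only uniform recharge is serialisable")
  if (!is.null(config$demand))
    raw$demand <- list(start = format(config$demand$start),
                       values = config$demand$values)
  if (length(config$contaminants))
    raw$contaminants <- lapply(unname(config$contaminants), function(cc)
      list(name = cc$name, retardation = cc$retardation, decay_rate = cc$decay_rate,
           disp_long = cc$disp_long, disp_transv = cc$disp_transv,
           mol_diffusion = cc$mol_diffusion, mcl = cc$mcl))
  if (length(config$settings)) raw$settings <- config$settings
  if (!is.null(config$interconnection)) raw$interconnection <- config$interconnection
  if (!is.null(config$network)) raw$network <- config$network
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
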