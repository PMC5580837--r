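#' Contaminant transport properties
#'
#' Dissolved-phase properties of one volatile organic compound (VOC): linear
#' sorption expressed as a retardation factor, first-order decay, and
#' dispersivities, together with its regulatory maximum contaminant level
#' (MCL).  Current US MCLs for the compounds this package was written around:
#' 5 ug/L for PCE, TCE and benzene, 2 ug/L for vinyl chloride, 100 ug/L for
#' trans-1,2-dichloroethylene.
#'
#' @param name Label, e.g. `"TCE"`.
#' @param retardation Dimensionless retardation factor, >= 1.
#' @param decay_rate First-order decay constant, 1/day, >= 0.
#' @param disp_long,disp_transv Longitudinal / transverse dispersivity, m.
#'   Requires `disp_transv <= disp_long`.
#' @param mol_diffusion Effective molecular diffusion, m2/day, >= 0.
#' @param mcl Maximum contaminant level, ug/L, > 0.
#' @return A `contaminant_spec` object.
#' @export
contaminant_spec <- function(name, retardation = 1, decay_rate = 0,
                             disp_long = 10, disp_transv = 1,
                             mol_diffusion = 0, mcl = 5) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x, nm, lo, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("contaminant_spec: ", nm, " must be a single number")
    if (if (strict) x <= lo else x < lo)
      stop("contaminant_spec: ", nm, " must be ", if (strict) "> " else ">= ", lo)
    as.numeric(x)
  }
  retardation <- num1(retardation, "retardation", 1)
  decay_rate <- num1(decay_rate, "decay_rate", 0)
  disp_long <- num1(disp_long, "disp_long", 0)
  disp_transv <- num1(disp_transv, "disp_transv", 0)
  mol_diffusion <- num1(mol_diffusion, "mol_diffusion", 0)
  mcl <- num1(mcl, "mcl", 0, strict = TRUE)
  if (disp_transv > disp_long)
    stop("contaminant_spec: disp_transv must not exceed disp_long")
  structure(list(name = name, retardation = retardation,
                 decay_rate = decay_rate, disp_long = disp_long,
                 disp_transv = disp_transv, mol_diffusion = mol_diffusion,
                 mcl = mcl),
            class = "contaminant_spec")
}

#' Finite-difference grid description
#'
#' A layered rectangular grid.  Layers are numbered from the top (layer 1)
#' and each carries a hydrologic role: `"aquifer"` layers transmit water
#' horizontally and vertically, `"aquitard"` layers only vertically (leakance).
#' The default stack is the 7-layer alternating aquifer/aquitard column common
#' in Coastal Plain settings, aquifers at layers 1, 3, 5, 7.
#'
#' @param nlay,nrow,ncol Positive integer grid dimensions.
#' @param dx,dy Cell size, m, > 0 (uniform).
#' @param layer_thickness Numeric vector, m, one per layer, > 0.
#' @param layer_role Character vector per layer: `"aquifer"` or `"aquitard"`.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(nlay = 7L, nrow, ncol, dx, dy,
                      layer_thickness,
                      layer_role = rep(c("aquifer", "aquitard"),
                                       length.out = nlay)) {
  nlay <- as.integer(nlay); nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (any(c(nlay, nrow, ncol) < 1L)) stop("grid_spec: dimensions must be >= 1")
  if (!is.numeric(dx) || dx <= 0 || !is.numeric(dy) || dy <= 0)
    stop("grid_spec: dx and dy must be > 0")
  layer_thickness <- as.numeric(layer_thickness)
  if (length(layer_thickness) != nlay || any(layer_thickness <= 0))
    stop("grid_spec: layer_thickness must be one positive value per layer")
  layer_role <- as.character(layer_role)
  if (length(layer_role) != nlay || !all(layer_role %in% c("aquifer", "aquitard")))
    stop("grid_spec: layer_role must be 'aquifer' or 'aquitard', one per layer")
  structure(list(nlay = nlay, nrow = nrow, ncol = ncol,
                 dx = as.numeric(dx), dy = as.numeric(dy),
                 layer_thickness = layer_thickness, layer_role = layer_role),
            class = "grid_spec")
}

#' Hydraulic properties per model layer
#'
#' @param kh,kv Horizontal / vertical hydraulic conductivity, m/day, > 0
#'   (one value per layer).
#' @param specific_storage Specific storage, 1/m, > 0.
#' @param porosity Effective porosity, in (0, 1).
#' @return A data.frame of class `layer_properties` with one row per layer.
#' @export
layer_properties <- function(kh, kv, specific_storage, porosity) {
  n <- length(kh)
  kv <- rep_len(as.numeric(kv), n)
  specific_storage <- rep_len(as.numeric(specific_storage), n)
  porosity <- rep_len(as.numeric(porosity), n)
  kh <- as.numeric(kh)
  if (any(kh <= 0) || any(kv <= 0)) stop("layer_properties: kh, kv must be > 0")
  if (any(specific_storage <= 0)) stop("layer_properties: specific_storage must be > 0")
  if (any(porosity <= 0 | porosity >= 1))
    stop("layer_properties: porosity must be in (0,1)")
  structure(data.frame(kh = kh, kv = kv, specific_storage = specific_storage,
                       porosity = porosity),
            class = c("layer_properties", "data.frame"))
}

#' Constant-concentration contaminant source
#'
#' A set of cells held at a fixed dissolved concentration over an inclusive
#' month window (a source "introduced" in its start month and "removed" after
#' its end month), the standard representation when source mass-release
#' histories are unknown but concentration/duration tables are documented.
#'
#' @param cells Integer matrix with columns `layer`, `row`, `col` (1-based).
#' @param concentration Source concentration, ug/L, > 0.
#' @param start,end `month_index` scalars, `start <= end`.
#' @return A `source_term` object.
#' @export
source_term <- function(cells, concentration, start, end) {
  cells <- as.matrix(cells)
  if (nrow(cells) < 1L || ncol(cells) != 3L)
    stop("source_term: cells must be a non-empty (layer,row,col) matrix")
  storage.mode(cells) <- "integer"
  colnames(cells) <- c("layer", "row", "col")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("source_term: concentration must be > 0")
  start <- as_month_index_like(start); end <- as_month_index_like(end)
  if (month_diff(start, end) > 0L) stop("source_term: start is after end")
  structure(list(cells = cells, concentration = as.numeric(concentration),
                 start = start, end = end),
            class = "source_term")
}

#' Water-supply well record
#'
#' A well at one (row, col) location, screened across one or more aquifer
#' layers, with a rated capacity and documented in-service windows (inclusive
#' month intervals; a well entering service mid-month counts as in service
#' for the whole month, consistent with monthly stress periods).
#'
#' @param id Label.
#' @param row,col 1-based cell indices.
#' @param screened_layers Integer vector of layer numbers (aquifer layers).
#' @param capacity Rated capacity, m3/day, > 0.
#' @param service_intervals List of `c(start, end)` pairs (`month_index` or
#'   "YYYY-MM"); must be ordered and non-overlapping.  Empty list = never in
#'   service.
#' @return A `well_record` object.
#' @export
well_record <- function(id, row, col, screened_layers, capacity,
                        service_intervals = list()) {
  stopifnot(length(id) == 1L)
  row <- as.integer(row); col <- as.integer(col)
  screened_layers <- sort(unique(as.integer(screened_layers)))
  if (length(screened_layers) < 1L)
    stop("well_record: at least one screened layer required (well ", id, ")")
  if (!is.numeric(capacity) || capacity <= 0)
    stop("well_record: capacity must be > 0 (well ", id, ")")
  iv <- lapply(service_intervals, function(p) {
    if (length(p) != 2L) stop("well_record: each service interval is (start, end)")
    elem <- function(i) if (inherits(p, "month_index")) p[i] else p[[i]]
    s <- as_month_index_like(elem(1L)); e <- as_month_index_like(elem(2L))
    if (month_diff(s, e) > 0L)
      stop("well_record: service interval start after end (well ", id, ")")
    list(start = s, end = e)
  })
  if (length(iv) > 1L) {
    starts <- vapply(iv, function(p) unclass(p$start), integer(1L))
    ends <- vapply(iv, function(p) unclass(p$end), integer(1L))
    o <- order(starts)
    iv <- iv[o]; starts <- starts[o]; ends <- ends[o]
    if (any(starts[-1L] <= ends[-length(ends)]))
      stop("well_record: overlapping service intervals (well ", id, ")")
  }
  structure(list(id = as.character(id), row = row, col = col,
                 screened_layers = screened_layers,
                 capacity = as.numeric(capacity), service_intervals = iv),
            class = "well_record")
}

#' Full physical description of a study site
#'
#' Everything the flow, transport and mixing stages need: the grid and layer
#' properties, head-controlling boundaries (constant-head cells and
#' head-dependent stream cells with fixed stage), areal recharge, contaminant
#' sources, supply wells, and the monthly simulation clock.
#'
#' @param grid A [grid_spec()].
#' @param layers A [layer_properties()] with `grid$nlay` rows.
#' @param constant_head_cells data.frame with columns `layer,row,col,head`
#'   (head in m); may be empty if stream cells exist.
#' @param stream_cells data.frame with columns
#'   `layer,row,col,stage,conductance` (m, m2/day); may be empty.
#' @param recharge Either a single rate or an `nrow x ncol` matrix, m/day,
#'   applied to layer 1.
#' @param sources List of [source_term()]s.
#' @param wells List of [well_record()]s.
#' @param clock_start,clock_end `month_index` scalars; span must be >= 12
#'   months.
#' @return A validated `site_model` object.
#' @export
site_model <- function(grid, layers, constant_head_cells = NULL,
                       stream_cells = NULL, recharge = 0,
                       sources = list(), wells = list(),
                       clock_start, clock_end) {
  stopifnot(inherits(grid, "grid_spec"), inherits(layers, "layer_properties"))
  if (nrow(layers) != grid$nlay)
    stop("site_model: layers must have one row per grid layer")
  chk_cells <- function(df, what, extra_cols = character()) {
    need <- c("layer", "row", "col", extra_cols)
    if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
      df <- as.data.frame(setNames(rep(list(numeric(0)), length(need)), need))
    }
    df <- as.data.frame(df)
    if (!all(need %in% names(df)))
      stop("site_model: ", what, " needs columns ", paste(need, collapse = ", "))
    bad <- df$layer < 1 | df$layer > grid$nlay |
      df$row < 1 | df$row > grid$nrow | df$col < 1 | df$col > grid$ncol
    if (any(bad)) stop("site_model: ", what, " references cells outside the grid")
    df[need]
  }
  constant_head_cells <- chk_cells(constant_head_cells, "constant_head_cells", "head")
  stream_cells <- chk_cells(stream_cells, "stream_cells", c("stage", "conductance"))
  if (nrow(stream_cells) > 0L && any(stream_cells$conductance <= 0))
    stop("site_model: stream conductance must be > 0")
  if (nrow(constant_head_cells) + nrow(stream_cells) == 0L)
    stop("site_model: at least one constant-head or stream cell is required")
  if (length(recharge) == 1L) {
    recharge <- matrix(as.numeric(recharge), grid$nrow, grid$ncol)
  } else {
    recharge <- as.matrix(recharge)
    if (!all(dim(recharge) == c(grid$nrow, grid$ncol)))
      stop("site_model: recharge must be scalar or nrow x ncol")
  }
  clock_start <- as_month_index_like(clock_start)
  clock_end <- as_month_index_like(clock_end)
  if (month_diff(clock_end, clock_start) + 1L < 12L)
    stop("site_model: clock must span at least 12 months")
  aq <- which(grid$layer_role == "aquifer")
  for (s in sources) {
    stopifnot(inherits(s, "source_term"))
    if (any(s$cells[, "layer"] < 1L | s$cells[, "layer"] > grid$nlay |
            s$cells[, "row"] < 1L | s$cells[, "row"] > grid$nrow |
            s$cells[, "col"] < 1L | s$cells[, "col"] > grid$ncol))
      stop("site_model: source cells outside the grid")
  }
  ids <- character(0)
  for (w in wells) {
    stopifnot(inherits(w, "well_record"))
    if (w$row < 1L || w$row > grid$nrow || w$col < 1L || w$col > grid$ncol)
      stop("site_model: well '", w$id, "' lies outside the grid")
    if (!all(w$screened_layers %in% aq))
      stop("site_model: well '", w$id, "' is screened in a non-aquifer layer")
    if (w$id %in% ids) stop("site_model: duplicate well id '", w$id, "'")
    ids <- c(ids, w$id)
  }
  structure(list(grid = grid, layers = layers,
                 constant_head_cells = constant_head_cells,
                 stream_cells = stream_cells, recharge = recharge,
                 sources = sources, wells = wells,
                 clock_start = clock_start, clock_end = clock_end),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<site_model> %d layers x %d rows x %d cols (%g x %g m cells)\n",
              g$nlay, g$nrow, g$ncol, g$dx, g$dy))
  cat(sprintf("  clock %s .. %s (%d months)\n", format(x$clock_start),
              format(x$clock_end), month_diff(x$clock_end, x$clock_start) + 1L))
  cat(sprintf("  %d constant-head cells, %d stream cells, %d sources, %d wells\n",
              nrow(x$constant_head_cells), nrow(x$stream_cells),
              length(x$sources), length(x$wells)))
  invisible(x)
}

#' Months of a site's simulation clock
#' @param site A `site_model`.
#' @return `month_index` vector covering the clock.
#' @export
site_clock <- function(site) month_range(site$clock_start, site$clock_end)

# linear index helpers over (layer, row, col), column-major by layer-fastest?
# We store fields as 3-d arrays [layer, row, col]; this maps triples to the
# corresponding flat index.
cell_index <- function(grid, layer, row, col) {
  (as.integer(col) - 1L) * grid$nlay * grid$nrow +
    (as.integer(row) - 1L) * grid$nlay + as.integer(layer)
}
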