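# Seeded generators of synthetic study areas.  The templates reproduce the
# *structure* the reconstruction assumes — a layered aquifer/aquitard stack,
# constant-concentration sources switched on in a known month, supply wells
# with documented service windows (including a late-starting well and a
# replacement pair), a stream boundary bending the plumes, sparse noisy
# observations, and partially documented interconnection histories — with no
# attempt to reproduce any real site's geometry or parameter values.

#' Generate a synthetic study site
#'
#' @param template One of `"industrial-area"` (multiple sources and wells
#'   feeding one WTP), `"landfill"` (a single late-starting well over a deep
#'   source) or `"two-system"` (industrial-area plus a second, initially
#'   uncontaminated distribution system, an interconnection history and a
#'   pipe network).
#' @param scale `"small"` (7 layers, 16 x 16 cells, 12-year clock) or
#'   `"medium"` (7 layers, 24 x 24 cells, 20-year clock).
#' @param seed Integer seed; the same `(template, scale, seed)` always
#'   yields an identical configuration.
#' @return A `site_config` (see [load_config()]): site, WTP demand,
#'   contaminants, settings, and for `"two-system"` the interconnection
#'   block and network.
#' @export
generate_site <- function(template = c("industrial-area", "landfill", "two-system"),
                          scale = c("small", "medium"), seed = 1L) {
  template <- match.arg(template)
  scale <- match.arg(scale)
  switch(template,
         "industrial-area" = site_industrial(scale, seed, two_system = FALSE),
         "landfill" = site_landfill(scale, seed),
         "two-system" = site_industrial(scale, seed, two_system = TRUE))
}

default_tce <- function() {
  contaminant_spec("TCE", retardation = 1.3, decay_rate = 5e-5,
                   disp_long = 15, disp_transv = 1.5, mol_diffusion = 0,
                   mcl = 5)
}

# Layer stack shared by the templates: 7 layers, aquifers at 1, 3, 5, 7.
template_stack <- function() {
  list(
    thickness = c(12, 4, 12, 4, 12, 4, 12),
    role = c("aquifer", "aquitard", "aquifer", "aquitard",
             "aquifer", "aquitard", "aquifer"),
    layers = layer_properties(
      kh = c(12, 0.01, 15, 0.01, 18, 0.01, 10),
      kv = c(1.2, 0.002, 1.5, 0.002, 1.8, 0.002, 1.0),
      specific_storage = c(2e-5, 1e-4, 2e-5, 1e-4, 2e-5, 1e-4, 2e-5),
      porosity = c(0.25, 0.35, 0.25, 0.35, 0.25, 0.35, 0.25)))
}

site_industrial <- function(scale, seed, two_system) {
  n <- if (scale == "small") 16L else 24L
  years <- if (scale == "small") 12L else 20L
  clock_start <- month_index(1951, 1)
  clock_end <- month_add(clock_start, years * 12L - 1L)
  stk <- template_stack()
  grid <- grid_spec(nlay = 7L, nrow = n, ncol = n, dx = 100, dy = 100,
                    layer_thickness = stk$thickness, layer_role = stk$role)
  edge <- expand.grid(layer = 1:7, row = seq_len(n))
  ch <- rbind(
    data.frame(layer = edge$layer, row = edge$row, col = 1L, head = 12),
    data.frame(layer = edge$layer, row = edge$row, col = n, head = 6))
  st <- data.frame(layer = 1L, row = seq_len(n), col = n - 2L,
                   stage = seq(7.2, 6.4, length.out = n), conductance = 150)

  cfg <- with_seed(sub_seed(seed, 1L), {
    n_src <- sample(2:3, 1L)
    mid <- round(n / 2)
    src_rows <- sort(sample(3:(n - 3L), n_src))
    sources <- lapply(seq_len(n_src), function(k) {
      r <- src_rows[k]
      cells <- expand.grid(layer = 1L, row = r:(r + 1L), col = 3:4)
      end <- if (k == 1L) clock_end else month_add(clock_start, 12L * sample(6:9, 1L))
      source_term(as.matrix(cells), concentration = round(stats::runif(1, 800, 1500)),
                  start = clock_start, end = end)
    })
    n_well <- if (scale == "small") 4L else 7L
    wcols <- sample((mid):(n - 5L), n_well, replace = TRUE)
    wrows <- sample(3:(n - 2L), n_well)
    caps <- round(stats::runif(n_well, 600, 1200))
    screens <- list(c(3L, 5L), 5L, c(5L, 7L), c(3L, 5L))
    wells <- vector("list", n_well)
    repl_end <- month_add(clock_start, 9L * 12L - 1L)
    for (k in seq_len(n_well)) {
      svc <- if (k == 2L) {
        list(c(month_add(clock_start, 24L), clock_end))        # late entrant
      } else if (k == 3L && n_well >= 4L) {
        list(c(clock_start, repl_end))                          # replaced well
      } else if (k == 4L && n_well >= 4L) {
        list(c(month_add(repl_end, 1L), clock_end))             # its replacement
      } else {
        list(c(clock_start, clock_end))
      }
      wells[[k]] <- well_record(id = sprintf("W-%02d", k), row = wrows[k],
                                col = wcols[k],
                                screened_layers = screens[[((k - 1L) %% 4L) + 1L]],
                                capacity = caps[k], service_intervals = svc)
    }
    list(sources = sources, wells = wells)
  })

  site <- site_model(grid = grid, layers = stk$layers,
                     constant_head_cells = ch, stream_cells = st,
                     recharge = 3e-4, sources = cfg$sources, wells = cfg$wells,
                     clock_start = clock_start, clock_end = clock_end)
  demand <- template_demand(site)
  interconnection <- NULL
  network <- NULL
  if (two_system) {
    cutover <- month_add(clock_start, 6L * 12L + 5L)   # June, year 7
    yrs <- seq(month_year(cutover), month_year(clock_end))
    hist <- generate_interconnection_history(
      years = yrs, months_active = 4:8, p_on = 0.35, persistence = 0.5,
      frac_documented = 0.5, seed = sub_seed(seed, 2L))
    interconnection <- list(
      cutover = format(cutover), years = yrs, months_active = 4:8,
      event_hours = 240, off_conc = 0, n_sims = 500L,
      records = lapply(seq_len(nrow(hist$records)), function(i)
        as.list(hist$records[i, ])),
      receiving_area = "receiving"
    )
    network <- template_network()
  }
  structure(list(site = site, demand = demand,
                 contaminants = list(TCE = default_tce()),
                 settings = list(substeps_per_month = 1L,
                                 truth_substeps_per_month = 3L),
                 interconnection = interconnection, network = network),
            class = "site_config")
}

site_landfill <- function(scale, seed) {
  n <- if (scale == "small") 14L else 20L
  years <- if (scale == "small") 12L else 20L
  clock_start <- month_index(1948, 1)
  clock_end <- month_add(clock_start, years * 12L - 1L)
  stk <- template_stack()
  grid <- grid_spec(nlay = 7L, nrow = n, ncol = n, dx = 100, dy = 100,
                    layer_thickness = stk$thickness, layer_role = stk$role)
  edge <- expand.grid(layer = 1:7, row = seq_len(n))
  ch <- rbind(
    data.frame(layer = edge$layer, row = edge$row, col = 1L, head = 10),
    data.frame(layer = edge$layer, row = edge$row, col = n, head = 5))
  st <- data.frame(layer = 1L, row = seq_len(n), col = n - 1L,
                   stage = seq(6.0, 5.4, length.out = n), conductance = 120)
  cfg <- with_seed(sub_seed(seed, 1L), {
    mid <- round(n / 2)
    # the landfill source penetrates the full stack (all 7 layers)
    cells <- expand.grid(layer = 1:7, row = (mid - 1L):mid, col = 3L)
    sources <- list(source_term(as.matrix(cells),
                                concentration = round(stats::runif(1, 1500, 3000)),
                                start = clock_start, end = clock_end))
    # exactly one well, beginning operations years after the source onset
    lag <- sample(5:7, 1L)
    svc_start <- month_index(month_year(clock_start) + lag, 7L)
    svc_end <- month_add(clock_end, -10L)
    wells <- list(well_record(id = "LF-01", row = mid, col = mid + 2L,
                              screened_layers = 5L,
                              capacity = round(stats::runif(1, 700, 1100)),
                              service_intervals = list(c(svc_start, svc_end))))
    list(sources = sources, wells = wells)
  })
  site <- site_model(grid = grid, layers = stk$layers,
                     constant_head_cells = ch, stream_cells = st,
                     recharge = 3e-4, sources = cfg$sources, wells = cfg$wells,
                     clock_start = clock_start, clock_end = clock_end)
  structure(list(site = site, demand = template_demand(site),
                 contaminants = list(TCE = default_tce()),
                 settings = list(substeps_per_month = 1L,
                                 truth_substeps_per_month = 3L),
                 interconnection = NULL, network = NULL),
            class = "site_config")
}

# WTP demand: 50% of the in-service capacity with a +/-10% seasonal swing,
# zero in months with no well in service.
template_demand <- function(site) {
  clock <- site_clock(site)
  svc <- service_matrix(site$wells, clock)
  caps <- vapply(site$wells, function(w) w$capacity, 1.0)
  cap_on <- as.vector(svc %*% caps)
  season <- 1 + 0.1 * sin(2 * pi * (month_of(clock) - 3) / 12)
  monthly_series(clock[1L], round(0.5 * cap_on * season, 3), units = "m3/day")
}

# Receiving-system pipe network for the two-system template: a boundary
# reservoir standing in for the contaminated upstream system, a booster pump,
# a trunk line, a near housing area and a distal housing area.
template_network <- function() {
  flat <- rep(1, 24)
  list(
    reservoir = list(id = "upstream", head = 60),
    junctions = list(
      list(id = "trunk1", elev = 10, demand = 0, area = "trunk"),
      list(id = "trunk2", elev = 10, demand = 200, area = "trunk"),
      list(id = "nearA", elev = 12, demand = 600, area = "near"),
      list(id = "nearB", elev = 12, demand = 500, area = "near"),
      list(id = "midA", elev = 14, demand = 400, area = "mid"),
      list(id = "farA", elev = 16, demand = 300, area = "distal"),
      list(id = "farB", elev = 16, demand = 250, area = "distal")),
    pumps = list(list(id = "booster", from = "upstream", to = "trunk1",
                      h0 = 55, r = 1e-6)),
    valves = list(list(id = "bypass", from = "upstream", to = "trunk1",
                       status = "closed")),
    pipes = list(
      list(id = "p1", from = "trunk1", to = "trunk2", length = 400, diameter = 0.35, roughness = 110),
      list(id = "p2", from = "trunk2", to = "nearA", length = 500, diameter = 0.3, roughness = 110),
      list(id = "p3", from = "nearA", to = "nearB", length = 400, diameter = 0.25, roughness = 110),
      list(id = "p4", from = "trunk2", to = "midA", length = 900, diameter = 0.25, roughness = 110),
      list(id = "p5", from = "midA", to = "farA", length = 1200, diameter = 0.2, roughness = 110),
      list(id = "p6", from = "farA", to = "farB", length = 600, diameter = 0.15, roughness = 110),
      list(id = "p7", from = "nearB", to = "midA", length = 700, diameter = 0.2, roughness = 110)),
    patterns = list(default = flat))
}

#' Generate a partially documented interconnection history
#'
#' Simulates the *true* monthly on/off transfer sequence over the active
#' season of each year from a two-state chain, then masks it so that only a
#' fraction of months carries a documented status.  The unmasked truth is
#' retained for parameter-recovery tests.
#'
#' The chain is parameterised by the marginal on-probability `p_on` and a
#' `persistence` weight: each month keeps the previous month's state with
#' probability `persistence` and otherwise redraws Bernoulli(`p_on`), so the
#' stationary on-fraction is `p_on` for any persistence.
#'
#' @param years Integer vector of calendar years (non-empty).
#' @param months_active Integer months 1--12 forming the season (non-empty).
#' @param p_on Marginal probability a month is "on", in [0,1].
#' @param persistence State-persistence weight, in [0,1].
#' @param frac_documented Probability a month's status is documented.
#' @param seed Integer seed.
#' @return List of class `interconnection_history`: `records` (the masked
#'   [interconnection_records()]), `truth` (0/1 integer vector),
#'   `months` (`month_index`), `chain` (the generating [two_state_chain()]).
#' @export
generate_interconnection_history <- function(years, months_active, p_on,
                                             persistence, frac_documented,
                                             seed = 1L) {
  if (length(years) == 0L || length(months_active) == 0L)
    stop("generate_interconnection_history: years and months_active must be non-empty")
  probs <- c(p_on = p_on, persistence = persistence,
             frac_documented = frac_documented)
  if (any(probs < 0 | probs > 1))
    stop("generate_interconnection_history: probabilities must lie in [0,1]")
  months_active <- sort(unique(as.integer(months_active)))
  months <- month_index(rep(years, each = length(months_active)),
                        rep(months_active, times = length(years)))
  chain <- two_state_chain(
    p_stay_on = persistence + (1 - persistence) * p_on,
    p_stay_off = persistence + (1 - persistence) * (1 - p_on),
    initial_p_on = p_on)
  nM <- length(months)
  truth <- integer(nM)
  out <- with_seed(seed, {
    yr <- month_year(months)
    serial <- unclass(months)
    prev_serial <- -Inf
    prev_state <- 0L
    for (i in seq_len(nM)) {
      new_seg <- (serial[i] - prev_serial != 1L)
      p <- if (new_seg) p_on else if (prev_state == 1L) chain$p_stay_on
      else 1 - chain$p_stay_off
      truth[i] <- stats::rbinom(1L, 1L, p)
      prev_serial <- serial[i]
      prev_state <- truth[i]
    }
    documented <- stats::runif(nM) < frac_documented
    H <- hours_in_month(months)
    hours <- ifelse(documented & truth == 1L,
                    round(pmin(stats::runif(nM, 24, 480), H)), NA_real_)
    status <- ifelse(!documented, "unknown",
                     ifelse(truth == 1L, "documented_on", "documented_off"))
    list(truth = truth, status = status, hours = hours)
  })
  records <- interconnection_records(months, out$status, out$hours)
  structure(list(records = records, truth = out$truth, months = months,
                 chain = chain),
            class = "interconnection_history")
}

#' Forward "truth" run of a synthetic scenario
#'
#' Runs the site's own forward operators — schedule reconstruction, steady
#' and transient flow, transport, well extraction, WTP mixing — at fine time
#' resolution (`truth_substeps_per_month`, default 3) to produce the truth
#' against which reconstructions, observation noise and uncertainty bands
#' are judged.
#'
#' @param config A `site_config` (from [generate_site()] or [load_config()]).
#' @param substeps_per_month Time resolution of the truth run.
#' @return A `scenario_truth`: list with `config`, `schedule`, `steady`,
#'   `heads`, `conc` (per contaminant), `well_series` (per contaminant),
#'   `wtp` (per contaminant [monthly_series]), `area_series`.
#' @export
make_scenario_truth <- function(config,
                                substeps_per_month =
                                  config$settings$truth_substeps_per_month %||% 3L) {
  site <- config$site
  schedule <- reconstruct_schedule(site$wells, config$demand)
  steady <- solve_steady_flow(site)
  heads <- solve_transient_flow(site, schedule, steady,
                                substeps_per_month = substeps_per_month)
  flows <- cell_flows(site, heads, schedule)
  conc <- list(); well_series <- list(); wtp <- list()
  for (cc in config$contaminants) {
    cf <- solve_transport(site, flows, cc,
                          substeps_per_month = substeps_per_month)
    ws <- extract_well_series(cf, site, schedule)
    mx <- mix_at_wtp(schedule, ws)
    conc[[cc$name]] <- cf
    well_series[[cc$name]] <- ws
    wtp[[cc$name]] <- mx$series
  }
  area_series <- lapply(wtp, function(s) list(primary = s))
  structure(list(config = config, schedule = schedule, steady = steady,
                 heads = heads, conc = conc, well_series = well_series,
                 wtp = wtp, area_series = area_series),
            class = "scenario_truth")
}

#' Sample sparse noisy observations from a scenario truth
#'
#' Head observations are drawn from the truth head fields at random cells
#' and months plus centred Gaussian noise; concentration observations are
#' drawn from the truth well series (pumping months only), 1 to a few
#' samples per well, with truncated-Gaussian (default) or multiplicative
#' log-normal noise — water-quality data are non-negative and right-skewed.
#'
#' @param truth A [make_scenario_truth()] result.
#' @param n_head Number of head observations.
#' @param samples_per_well Length-2 integer range; each well's sample count
#'   is uniform in it.
#' @param noise_sd Named vector `c(head = metres, conc = ug/L)`; for
#'   `conc_noise = "lognormal"` the conc entry is the log-sd.
#' @param seed Integer seed.
#' @param conc_noise `"truncnorm"` or `"lognormal"`.
#' @param contaminant Contaminant name (default: first).
#' @return An `observation_set`: list with `head_obs`, `conc_obs`,
#'   `noise_sd`.
#' @export
sample_observations <- function(truth, n_head = 50L, samples_per_well = c(1L, 5L),
                                noise_sd = c(head = 0.3, conc = 5),
                                seed = 1L, conc_noise = c("truncnorm", "lognormal"),
                                contaminant = NULL) {
  conc_noise <- match.arg(conc_noise)
  if (n_head < 0L || any(samples_per_well < 0L))
    stop("sample_observations: counts must be >= 0")
  if (any(noise_sd < 0)) stop("sample_observations: noise_sd must be >= 0")
  site <- truth$config$site
  g <- site$grid
  months <- site_clock(site)
  if (is.null(contaminant)) contaminant <- names(truth$well_series)[1L]
  ws <- truth$well_series[[contaminant]]
  with_seed(seed, {
    aq <- which(g$layer_role == "aquifer")
    ncell <- length(aq) * g$nrow * g$ncol * length(months)
    if (n_head > ncell)
      stop("sample_observations: n_head exceeds available cell-months")
    head_obs <- NULL
    if (n_head > 0L) {
      lay <- sample(aq, n_head, replace = TRUE)
      row <- sample(g$nrow, n_head, replace = TRUE)
      col <- sample(g$ncol, n_head, replace = TRUE)
      mi <- sample(length(months), n_head, replace = TRUE)
      tru <- vapply(seq_len(n_head), function(i)
        truth$heads$heads[[mi[i]]][lay[i], row[i], col[i]], 1.0)
      head_obs <- data.frame(layer = lay, row = row, col = col,
                             month = format(months[mi]),
                             head = tru + stats::rnorm(n_head, 0, noise_sd[["head"]]),
                             truth = tru, stringsAsFactors = FALSE)
    }
    conc_rows <- list()
    for (id in names(ws)) {
      s <- ws[[id]]
      avail <- which(!is.na(s$values))
      if (length(avail) == 0L) next
      k <- if (samples_per_well[1L] == samples_per_well[2L]) samples_per_well[1L]
      else sample(seq.int(samples_per_well[1L], samples_per_well[2L]), 1L)
      if (k == 0L) next
      if (k > length(avail))
        stop("sample_observations: requested ", k, " samples but well '", id,
             "' pumps in only ", length(avail), " months")
      pick <- sort(sample(avail, k))
      tru <- s$values[pick]
      obs <- if (conc_noise == "truncnorm") {
        pmax(0, tru + stats::rnorm(k, 0, noise_sd[["conc"]]))
      } else {
        tru * stats::rlnorm(k, 0, noise_sd[["conc"]])
      }
      conc_rows[[id]] <- data.frame(well = id,
                                    month = format(series_months(s)[pick]),
                                    concentration = obs, truth = tru,
                                    stringsAsFactors = FALSE)
    }
    conc_obs <- if (length(conc_rows)) do.call(rbind, conc_rows) else
      data.frame(well = character(0), month = character(0),
                 concentration = numeric(0), truth = numeric(0))
    rownames(conc_obs) <- NULL
    structure(list(head_obs = head_obs, conc_obs = conc_obs,
                   noise_sd = noise_sd),
              class = "observation_set")
  })
}
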