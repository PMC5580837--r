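# Pipeline orchestration: schedule -> flow -> transport -> well series ->
# WTP mixing -> (optional) interconnection + network blending -> exposure
# table.  The historical calibration loop (compare residuals, adjust
# parameters, re-run) is deliberately manual: the tooling provides the
# residual report and the OAT/uncertainty machinery, not an optimizer.  The
# pipeline has no health-outcome inputs anywhere: exposure reconstruction is
# structurally blinded to outcomes.

#' WTP monthly series from a raw configuration
#'
#' The standard stage composition used by the sensitivity and uncertainty
#' tools: parse the configuration, reconstruct the pumping schedule, solve
#' steady + transient flow, run transport for one contaminant, extract
#' flow-weighted well series and mix at the WTP.
#'
#' @param raw Raw configuration list (see [parse_config()]) or a
#'   `site_config`.
#' @param contaminant Contaminant name (default the first configured).
#' @return A [monthly_series] of WTP treated-water concentration.
#' @export
pipeline_wtp_series <- function(raw, contaminant = NULL) {
  config <- if (inherits(raw, "site_config")) raw else parse_config(raw)
  site <- config$site
  if (is.null(config$demand)) stop("pipeline_wtp_series: config has no demand")
  if (length(config$contaminants) == 0L)
    stop("pipeline_wtp_series: config has no contaminants")
  cc <- if (is.null(contaminant)) config$contaminants[[1L]]
  else config$contaminants[[contaminant]]
  substeps <- config$settings$substeps_per_month %||% 1L
  schedule <- reconstruct_schedule(site$wells, config$demand)
  steady <- solve_steady_flow(site)
  heads <- solve_transient_flow(site, schedule, steady,
                                substeps_per_month = substeps)
  flows <- cell_flows(site, heads, schedule)
  cf <- solve_transport(site, flows, cc, substeps_per_month = substeps)
  ws <- extract_well_series(cf, site, schedule)
  mix_at_wtp(schedule, ws)$series
}

#' Run the full historical reconstruction
#'
#' Executes every stage on a configuration and assembles the
#' epidemiology-facing exposure table: monthly mean concentration per
#' (location, contaminant) with MCL-exceedance flags and, optionally,
#' Monte-Carlo uncertainty bands for the primary service area.
#'
#' Service-area assignment: locations served by the primary WTP take its
#' mixed series; a receiving system (two-system sites) takes the primary
#' series directly before its own plant's cutover month, and afterwards the
#' event-blended series from the Markov interconnection model combined with
#' network transport gains.
#'
#' @param config A `site_config`, or a path to a YAML configuration.
#' @param out_dir Optional output directory: when given, [write_report()] is
#'   called on the results.
#' @param seed Integer seed for the interconnection simulation (and any
#'   other stochastic stage), fanned out by [sub_seed()].
#' @param uncertainty Optional list `(params, n, method)` propagated with
#'   [propagate()] to attach lo/hi bands to the primary location.
#' @return A `reconstruction`: list with `table` (the exposure
#'   data.frame), `manifest`, `wtp` (per contaminant), `schedule`,
#'   `heads`, `event` (or NULL), `area_gain` (or NULL).
#' @export
run_reconstruction <- function(config, out_dir = NULL, seed = 1L,
                               uncertainty = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "site_config"))
  site <- config$site
  substeps <- config$settings$substeps_per_month %||% 1L
  schedule <- reconstruct_schedule(site$wells, config$demand)
  steady <- solve_steady_flow(site)
  heads <- solve_transient_flow(site, schedule, steady,
                                substeps_per_month = substeps)
  flows <- cell_flows(site, heads, schedule)
  wtp <- list()
  for (cc in config$contaminants) {
    cf <- solve_transport(site, flows, cc, substeps_per_month = substeps)
    ws <- extract_well_series(cf, site, schedule)
    wtp[[cc$name]] <- mix_at_wtp(schedule, ws)$series
  }

  # interconnection + network blending for a receiving system
  event <- NULL; area_gain <- NULL; receiving <- list()
  ic <- config$interconnection
  if (!is.null(ic)) {
    records <- interconnection_history_records(ic)
    chain <- fit_chain(records, pseudocount = ic$pseudocount %||% 0.5)
    event <- simulate_events(chain, years = unlist(ic$years),
                             months_active = unlist(ic$months_active),
                             records = records,
                             n_sims = ic$n_sims %||% 500L,
                             seed = sub_seed(seed, 3L))
    net <- pipe_network_from_list(config$network)
    # conservative transport is linear in the source concentration: run the
    # event scenario once at unit concentration and scale by the monthly
    # upstream WTP value
    sc <- run_event_scenario(net, list(type = "pump"), source_conc = 1,
                             duration = ic$event_hours %||% 240, step = 1)
    area_gain <- sc$area_means
    cutover <- as_month_index(ic$cutover)
    for (cc in config$contaminants) {
      src <- wtp[[cc$name]]
      for (a in names(area_gain)) {
        on_conc <- monthly_series(src$start,
                                  ifelse(is.na(src$values), NA, src$values * area_gain[[a]]))
        blended <- blend_monthly(event, on_conc = on_conc,
                                 off_conc = ic$off_conc %||% 0,
                                 event_hours = ic$event_hours %||% 240)
        receiving[[cc$name]][[a]] <- blended
      }
    }
  }

  unc <- NULL
  if (!is.null(uncertainty)) {
    unc <- propagate(function(raw) pipeline_wtp_series(raw),
                     config, uncertainty$params,
                     n = uncertainty$n %||% 100L,
                     seed = sub_seed(seed, 4L),
                     method = uncertainty$method %||% "lhs")
  }

  rows <- list()
  clock <- site_clock(site)
  for (cc in config$contaminants) {
    s <- wtp[[cc$name]]
    vals <- series_get(s, clock)
    lo <- hi <- rep(NA_real_, length(clock))
    if (!is.null(unc)) {
      pos <- match(unclass(clock), unclass(unc$months))
      lo <- unc$percentiles[pos, "p2.5"]
      hi <- unc$percentiles[pos, "p97.5"]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      month = format(clock), location = "primary", contaminant = cc$name,
      mean = vals, lo = lo, hi = hi,
      exceeds_mcl = !is.na(vals) & vals > cc$mcl, stringsAsFactors = FALSE)
    if (!is.null(ic)) {
      cutover <- as_month_index(ic$cutover)
      for (a in names(receiving[[cc$name]])) {
        bl <- receiving[[cc$name]][[a]]
        rv <- ifelse(unclass(clock) < unclass(cutover), vals,
                     series_get(bl, clock))
        rv[unclass(clock) >= unclass(cutover) & is.na(series_get(bl, clock))] <-
          ic$off_conc %||% 0
        rows[[length(rows) + 1L]] <- data.frame(
          month = format(clock), location = paste0("receiving-", a),
          contaminant = cc$name, mean = rv, lo = NA_real_, hi = NA_real_,
          exceeds_mcl = !is.na(rv) & rv > cc$mcl, stringsAsFactors = FALSE)
      }
    }
  }
  table <- do.call(rbind, rows)
  manifest <- run_manifest(config, seed, out_dir)
  out <- structure(list(table = table, manifest = manifest, wtp = wtp,
                        schedule = schedule, heads = heads, event = event,
                        area_gain = area_gain, uncertainty = unc,
                        config = config),
                   class = "reconstruction")
  if (!is.null(out_dir)) write_report(table, manifest, out_dir, wtp = wtp,
                                      config = config)
  out
}

interconnection_history_records <- function(ic) {
  recs <- ic$records
  if (inherits(recs, "interconnection_records")) return(recs)
  interconnection_records(
    month = vapply(recs, function(r) r$month, ""),
    status = vapply(recs, function(r) r$status, ""),
    hours = vapply(recs, function(r) as.numeric(r$hours %||% NA_real_), 1.0))
}

run_manifest <- function(config, seed, out_dir) {
  raw <- config_to_list(config)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, tmp, precision = 15L)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config_hash = hash, seed = seed,
       package_version = as.character(utils::packageVersion("aquarecon")),
       created = format(Sys.time(), tz = "UTC"),
       out_dir = out_dir %||% NA_character_)
}

#' Summarise MCL exceedances of an exposure table
#'
#' @param table An exposure table from [run_reconstruction()].
#' @param mcls Named MCL vector per contaminant (defaults to 5 ug/L each if
#'   not given; [run_reconstruction()] output stores exceedance flags, so
#'   the flags themselves are summarised).
#' @return data.frame per (location, contaminant): `first`, `last` exceeded
#'   month, `total_months`, `peak`, `peak_month`.
#' @export
summarize_exceedances <- function(table, mcls = NULL) {
  if (nrow(table) == 0L) stop("summarize_exceedances: empty table")
  sp <- split(table, list(table$location, table$contaminant), drop = TRUE)
  rows <- lapply(sp, function(df) {
    df <- df[order(df$month), , drop = FALSE]
    ex <- df[df$exceeds_mcl, , drop = FALSE]
    pk <- if (all(is.na(df$mean))) c(NA_real_, NA_character_) else {
      i <- which.max(df$mean); list(df$mean[i], df$month[i])
    }
    data.frame(location = df$location[1L], contaminant = df$contaminant[1L],
               first = if (nrow(ex)) ex$month[1L] else NA_character_,
               last = if (nrow(ex)) ex$month[nrow(ex)] else NA_character_,
               total_months = nrow(ex),
               peak = as.numeric(pk[[1L]]), peak_month = as.character(pk[[2L]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$total_months > 0 | !is.na(out$peak), , drop = FALSE]
}

#' Write reconstruction reports
#'
#' Writes the exposure table and exceedance summary as RFC-4180 CSVs (ISO
#' `YYYY-MM` month stamps), a plain-text summary, and the run manifest.
#' Re-running with the same configuration and seed reproduces the CSVs
#' byte-for-byte.
#'
#' @param table Exposure table.
#' @param manifest Run manifest list.
#' @param out_dir Output directory (created if needed).
#' @param wtp Optional per-contaminant WTP series, also written as CSV.
#' @param config Optional `site_config`, serialised alongside.
#' @param plots If `TRUE` and ggplot2 is installed, writes time-series
#'   plots.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(table, manifest, out_dir, wtp = NULL, config = NULL,
                         plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(out_dir, "exposure_table.csv")
  utils::write.csv(table, f, row.names = FALSE)
  files <- c(files, f)
  summ <- if (nrow(table)) summarize_exceedances(table) else NULL
  f <- file.path(out_dir, "exceedance_summary.csv")
  utils::write.csv(summ %||% data.frame(), f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(wtp)) {
    months <- format(series_months(wtp[[1L]]))
    df <- data.frame(month = months)
    for (nm in names(wtp)) df[[nm]] <- wtp[[nm]]$values
    f <- file.path(out_dir, "wtp_series.csv")
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(config)) {
    f <- file.path(out_dir, "config.yaml")
    write_config(config, f)
    files <- c(files, f)
  }
  txt <- file.path(out_dir, "summary.txt")
  con <- file(txt, "w")
  if (nrow(table) == 0L || all(is.na(table$mean))) {
    writeLines("no data", con)
  } else {
    writeLines("Reconstruction summary", con)
    writeLines(sprintf("config hash: %s  seed: %d", manifest$config_hash,
                       manifest$seed), con)
    if (!is.null(summ) && nrow(summ)) {
      for (i in seq_len(nrow(summ))) {
        writeLines(sprintf(
          "%s / %s: peak %.3g ug/L in %s; MCL exceeded %d months (%s .. %s)",
          summ$location[i], summ$contaminant[i], summ$peak[i],
          summ$peak_month[i], summ$total_months[i],
          ifelse(is.na(summ$first[i]), "-", summ$first[i]),
          ifelse(is.na(summ$last[i]), "-", summ$last[i])), con)
      }
    } else writeLines("no MCL exceedances", con)
  }
  close(con)
  files <- c(files, txt)
  f <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, f)
  files <- c(files, f)
  if (plots && requireNamespace("ggplot2", quietly = TRUE) && nrow(table)) {
    p <- ggplot2::ggplot(table,
                         ggplot2::aes(x = as.Date(paste0(month, "-01")),
                                      y = mean, colour = location)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~contaminant, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "concentration (ug/L)")
    f <- file.path(out_dir, "series.pdf")
    ggplot2::ggsave(f, p, width = 8, height = 5)
    files <- c(files, f)
  }
  invisible(files)
}
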