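# One-at-a-time sensitivity and Monte Carlo / Latin-hypercube uncertainty
# propagation through any composition of the pipeline stages.  Parameters
# address numeric fields of the raw (list-form) site configuration by dotted
# path, so any config field is sweepable without code changes; a parameter
# may act on the field absolutely or as a multiplier (useful for vector
# fields such as a monthly demand series).

#' Uncertain-parameter specification
#'
#' @param path Dotted path into the raw configuration list, with integer
#'   components indexing list entries: e.g. `"recharge"`,
#'   `"sources.1.concentration"`, `"layers.3.kh"`, `"demand.values"`.
#' @param distribution One of `"uniform"`, `"log-uniform"`, `"normal"`,
#'   `"log-normal"`, `"triangular"`.
#' @param min,max Bounds (required for uniform, log-uniform, triangular;
#'   for the normal families the sweep range defaults to +/- 3 sd).
#' @param mean,sd Normal parameters; `meanlog`,`sdlog` for log-normal.
#' @param mode Triangular mode.
#' @param action `"absolute"` (replace the field) or `"multiplier"`
#'   (multiply the existing value, element-wise for vectors).
#' @return A `param_spec` object.
#' @export
param_spec <- function(path, distribution = c("uniform", "log-uniform",
                                              "normal", "log-normal",
                                              "triangular"),
                       min = NULL, max = NULL, mean = NULL, sd = NULL,
                       meanlog = NULL, sdlog = NULL, mode = NULL,
                       action = c("absolute", "multiplier")) {
  distribution <- match.arg(distribution)
  action <- match.arg(action)
  need <- function(x, nm) {
    if (is.null(x) || !is.finite(x))
      stop("param_spec(", path, "): ", nm, " required for ", distribution)
    x
  }
  p <- list(path = path, distribution = distribution, action = action)
  if (distribution %in% c("uniform", "log-uniform", "triangular")) {
    p$min <- need(min, "min"); p$max <- need(max, "max")
    if (p$min >= p$max) stop("param_spec(", path, "): min must be < max")
    if (distribution == "log-uniform" && p$min <= 0)
      stop("param_spec(", path, "): log-uniform needs positive support")
    if (distribution == "triangular") {
      p$mode <- need(mode, "mode")
      if (p$mode < p$min || p$mode > p$max)
        stop("param_spec(", path, "): mode must lie in [min, max]")
    }
  } else if (distribution == "normal") {
    p$mean <- need(mean, "mean"); p$sd <- need(sd, "sd")
    if (p$sd < 0) stop("param_spec(", path, "): sd must be >= 0")
  } else {
    p$meanlog <- need(meanlog, "meanlog"); p$sdlog <- need(sdlog, "sdlog")
    if (p$sdlog < 0) stop("param_spec(", path, "): sdlog must be >= 0")
  }
  structure(p, class = "param_spec")
}

param_quantile <- function(p, u) {
  switch(p$distribution,
         "uniform" = stats::qunif(u, p$min, p$max),
         "log-uniform" = exp(stats::qunif(u, log(p$min), log(p$max))),
         "normal" = stats::qnorm(u, p$mean, p$sd),
         "log-normal" = stats::qlnorm(u, p$meanlog, p$sdlog),
         "triangular" = qtriangular(u, p$min, p$mode, p$max))
}

qtriangular <- function(u, a, m, b) {
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

param_bounds <- function(p) {
  switch(p$distribution,
         "uniform" = , "log-uniform" = , "triangular" = c(p$min, p$max),
         "normal" = c(p$mean - 3 * p$sd, p$mean + 3 * p$sd),
         "log-normal" = exp(c(p$meanlog - 3 * p$sdlog, p$meanlog + 3 * p$sdlog)))
}

# get / set a numeric field of a nested list by dotted path
path_get <- function(lst, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  for (p in parts) {
    idx <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if (is.numeric(idx)) {
      if (idx > length(lst)) stop("parameter path not found: ", path)
      lst <- lst[[idx]]
    } else {
      if (!is.list(lst) || is.null(lst[[idx]]))
        stop("parameter path not found: ", path)
      lst <- lst[[idx]]
    }
  }
  lst
}

path_set <- function(lst, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(node, parts) {
    p <- parts[1L]
    idx <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
    if (is.numeric(idx) && idx > length(node)) stop("parameter path not found: ", path)
    if (!is.numeric(idx) && (!is.list(node) || is.null(node[[idx]])))
      stop("parameter path not found: ", path)
    if (length(parts) == 1L) node[[idx]] <- value
    else node[[idx]] <- rec(node[[idx]], parts[-1L])
    node
  }
  rec(lst, parts)
}

apply_params <- function(raw, params, values) {
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (p$action == "multiplier") {
      cur <- path_get(raw, p$path)
      raw <- path_set(raw, p$path, as.numeric(cur) * values[k])
    } else {
      raw <- path_set(raw, p$path, values[k])
    }
  }
  raw
}

#' Latin-hypercube parameter sample
#'
#' Stratified sample: for each parameter, the `n` draws occupy each of the
#' `n` equal-probability strata exactly once, with strata permuted
#' independently per parameter, then mapped through the parameter's
#' quantile function.
#'
#' @param params List of [param_spec()]s.
#' @param n Number of draws, >= 1.
#' @param seed Integer seed (same seed, same matrix).
#' @return `n x length(params)` matrix, columns named by parameter path.
#' @export
lhs_sample <- function(params, n, seed = 1L) {
  if (n < 1L) stop("lhs_sample: n must be >= 1")
  k <- length(params)
  U <- with_seed(seed, lhs::randomLHS(as.integer(n), max(k, 1L)))
  out <- vapply(seq_len(k), function(j) param_quantile(params[[j]], U[, j]),
                numeric(n))
  out <- matrix(out, nrow = n, ncol = k)
  colnames(out) <- vapply(params, function(p) p$path, "")
  out
}

#' One-at-a-time sensitivity sweep
#'
#' Evaluates a pipeline at `n_points` values of a single parameter spanning
#' its bounds (log-spaced for the log families), all other inputs at their
#' nominal configuration values.
#'
#' @param pipeline Function `(raw_config) -> monthly_series or numeric`.
#' @param config Nominal configuration: a `site_config` or raw list.
#' @param param A [param_spec()].
#' @param n_points Number of evaluation points, >= 2.
#' @return data.frame of class `oat_curve` with columns `path`, `value`,
#'   `output` (series peak if the pipeline returns a series) and, for series
#'   output, `peak_month`.
#' @export
oat_sweep <- function(pipeline, config, param, n_points = 5L) {
  if (n_points < 2L) stop("oat_sweep: n_points must be >= 2")
  raw <- if (inherits(config, "site_config")) config_to_list(config) else config
  path_get(raw, param$path)   # fail fast on a bad path
  b <- param_bounds(param)
  vals <- if (param$distribution %in% c("log-uniform", "log-normal")) {
    exp(seq(log(b[1L]), log(b[2L]), length.out = n_points))
  } else seq(b[1L], b[2L], length.out = n_points)
  rows <- lapply(vals, function(v) {
    out <- pipeline(apply_params(raw, list(param), v))
    if (inherits(out, "monthly_series")) {
      pk <- series_peak(out)
      data.frame(path = param$path, value = v, output = pk$value,
                 peak_month = format(pk$month), stringsAsFactors = FALSE)
    } else {
      data.frame(path = param$path, value = v, output = as.numeric(out),
                 peak_month = NA_character_, stringsAsFactors = FALSE)
    }
  })
  structure(do.call(rbind, rows), class = c("oat_curve", "data.frame"))
}

#' Monte Carlo / Latin-hypercube uncertainty propagation
#'
#' Runs the pipeline once per parameter realization and aggregates the
#' monthly 2.5/25/50/75/97.5 percentiles.  Realizations that fail (e.g. a
#' capacity shortfall under an extreme demand draw) are recorded, not
#' silently dropped; more than 20% failures aborts the batch.
#'
#' @param pipeline Function `(raw_config) -> monthly_series`.
#' @param config Nominal configuration (`site_config` or raw list).
#' @param params List of [param_spec()]s.
#' @param n Number of realizations.
#' @param seed Integer seed (drives sampling and any pipeline substreams).
#' @param method `"lhs"` (default) or `"mc"` (simple random sampling).
#' @return An `uncertainty_result`: list with `months`, `percentiles`
#'   (months x 5 matrix), `realizations` (months x n matrix, `NA` columns
#'   for failures), `draws`, `n`, `n_failed`, `failures` (messages),
#'   `seed`, `method`.
#' @export
propagate <- function(pipeline, config, params, n = 100L, seed = 1L,
                      method = c("lhs", "mc")) {
  method <- match.arg(method)
  raw <- if (inherits(config, "site_config")) config_to_list(config) else config
  draws <- if (method == "lhs") {
    lhs_sample(params, n, seed = sub_seed(seed, 1L))
  } else {
    k <- length(params)
    U <- with_seed(sub_seed(seed, 1L), matrix(stats::runif(n * k), n, k))
    m <- vapply(seq_len(k), function(j) param_quantile(params[[j]], U[, j]),
                numeric(n))
    m <- matrix(m, nrow = n, ncol = k,
                dimnames = list(NULL, vapply(params, function(p) p$path, "")))
    m
  }
  reals <- NULL
  months <- NULL
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(pipeline(apply_params(raw, params, draws[i, ])),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      if (!is.null(reals)) reals[, i] <- NA_real_
      next
    }
    if (!inherits(res, "monthly_series"))
      stop("propagate: pipeline must return a monthly_series")
    if (is.null(reals)) {
      months <- series_months(res)
      reals <- matrix(NA_real_, length(months), n)
      if (length(failures)) reals[, seq_along(failures)] <- NA_real_
    }
    reals[, i] <- res$values
  }
  if (is.null(reals)) stop("propagate: every realization failed")
  n_failed <- length(failures)
  if (n_failed > 0.2 * n)
    stop("propagate: ", n_failed, "/", n, " realizations failed; first error: ",
         failures[1L])
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  perc <- t(apply(reals, 1L, stats::quantile, probs = probs, na.rm = TRUE))
  colnames(perc) <- paste0("p", probs * 100)
  structure(list(months = months, percentiles = perc, realizations = reals,
                 draws = draws, n = n, n_failed = n_failed,
                 failures = failures, seed = seed, method = method),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result> %d months x %d realizations (%s), %d failed\n",
              nrow(x$percentiles), x$n, x$method, x$n_failed))
  invisible(x)
}

#' Uncertainty ratio at the peak month
#'
#' The 97.5th / 2.5th percentile ratio at the month where the median series
#' peaks: a one-number summary of how much reconstructed concentrations
#' range across realizations.
#'
#' @param result An `uncertainty_result`.
#' @return A single ratio (Inf if the 2.5th percentile is 0).
#' @export
uncertainty_ratio <- function(result) {
  pk <- which.max(result$percentiles[, "p50"])
  hi <- result$percentiles[pk, "p97.5"]
  lo <- result$percentiles[pk, "p2.5"]
  if (lo <= 0) Inf else hi / lo
}
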