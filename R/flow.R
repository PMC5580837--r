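# ---- internal: finite-difference plumbing -----------------------------------
#
# Fields live in 3-d arrays dim = c(nlay, nrow, ncol); the flat (column-major)
# index therefore runs layer-fastest and agrees with cell_index().
#
# Conductances follow the standard block-centred scheme: horizontal
# conductance between adjacent cells is the harmonic mean of layer
# transmissivity (kh * thickness) scaled by face width / spacing; aquitard
# layers have zero horizontal conductance (vertical-leakance representation).
# Vertical conductance between stacked cells is the series combination of the
# two half-cell leakances (kv / half-thickness) times the cell plan area.

flow_geometry <- function(site) {
  g <- site$grid
  nl <- g$nlay; nr <- g$nrow; nc <- g$ncol
  dz <- g$layer_thickness
  Tl <- ifelse(g$layer_role == "aquifer", site$layers$kh * dz, 0)
  cx_l <- g$dy * Tl / g$dx          # conductance per x-face, by layer
  cy_l <- g$dx * Tl / g$dy
  cz_l <- if (nl > 1L) {
    g$dx * g$dy / (dz[-nl] / (2 * site$layers$kv[-nl]) +
                     dz[-1L] / (2 * site$layers$kv[-1L]))
  } else numeric(0)
  N <- nl * nr * nc
  idx <- function(l, r, c) cell_index(g, l, r, c)

  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  add_faces <- function(i, j, cond) {
    keep <- cond > 0
    list(i = i[keep], j = j[keep], x = cond[keep])
  }
  # x-faces
  if (nc > 1L) {
    f <- expand.grid(l = seq_len(nl), r = seq_len(nr), c = seq_len(nc - 1L))
    fx <- add_faces(idx(f$l, f$r, f$c), idx(f$l, f$r, f$c + 1L), cx_l[f$l])
  } else fx <- list(i = integer(0), j = integer(0), x = numeric(0))
  # y-faces
  if (nr > 1L) {
    f <- expand.grid(l = seq_len(nl), r = seq_len(nr - 1L), c = seq_len(nc))
    fy <- add_faces(idx(f$l, f$r, f$c), idx(f$l, f$r + 1L, f$c), cy_l[f$l])
  } else fy <- list(i = integer(0), j = integer(0), x = numeric(0))
  # z-faces
  if (nl > 1L) {
    f <- expand.grid(l = seq_len(nl - 1L), r = seq_len(nr), c = seq_len(nc))
    fz <- add_faces(idx(f$l, f$r, f$c), idx(f$l + 1L, f$r, f$c), cz_l[f$l])
  } else fz <- list(i = integer(0), j = integer(0), x = numeric(0))

  list(N = N, nl = nl, nr = nr, nc = nc, idx = idx,
       faces = list(x = fx, y = fy, z = fz),
       cx_l = cx_l, cy_l = cy_l, cz_l = cz_l,
       cell_area = g$dx * g$dy,
       cell_storage = site$layers$specific_storage * dz * g$dx * g$dy,
       pore_volume = site$layers$porosity * dz * g$dx * g$dy)
}

# Assemble the (symmetric) conductance Laplacian + stream-leakage diagonal,
# the base RHS (recharge + stream stage terms), and the Dirichlet bookkeeping.
flow_system <- function(site, geom) {
  faces <- geom$faces
  i <- c(faces$x$i, faces$y$i, faces$z$i)
  j <- c(faces$x$j, faces$y$j, faces$z$j)
  x <- c(faces$x$x, faces$y$x, faces$z$x)
  diag_add <- numeric(geom$N)
  b <- numeric(geom$N)

  st <- site$stream_cells
  if (nrow(st) > 0L) {
    k <- geom$idx(st$layer, st$row, st$col)
    diag_add[k] <- diag_add[k] + st$conductance
    b[k] <- b[k] + st$conductance * st$stage
  }
  # recharge into layer 1
  rc <- expand.grid(r = seq_len(geom$nr), c = seq_len(geom$nc))
  k1 <- geom$idx(1L, rc$r, rc$c)
  b[k1] <- b[k1] + site$recharge[cbind(rc$r, rc$c)] * geom$cell_area

  diag_total <- diag_add + tabulate_weighted(c(i, j), c(x, x), geom$N)
  A <- Matrix::sparseMatrix(
    i = c(i, j, seq_len(geom$N)),
    j = c(j, i, seq_len(geom$N)),
    x = c(-x, -x, diag_total),
    dims = c(geom$N, geom$N))

  dir <- rep(FALSE, geom$N)
  hdir <- numeric(geom$N)
  ch <- site$constant_head_cells
  if (nrow(ch) > 0L) {
    k <- geom$idx(ch$layer, ch$row, ch$col)
    dir[k] <- TRUE
    hdir[k] <- ch$head
  }
  if (!any(dir) && nrow(st) == 0L)
    stop("flow: no head-controlling boundary (constant-head or stream cells)")
  list(A = A, b = b, dir = dir, hdir = hdir)
}

tabulate_weighted <- function(bins, w, n) {
  out <- numeric(n)
  if (length(bins) > 0L) {
    s <- rowsum(w, group = bins)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# Transmissivity-share weights for a well's screened layers (fixed a priori;
# the same weights apportion pumping in the flow solver and average
# concentrations in the transport extraction).
well_layer_weights <- function(site, well) {
  Tl <- site$layers$kh[well$screened_layers] *
    site$grid$layer_thickness[well$screened_layers]
  Tl / sum(Tl)
}

# Per-cell well extraction vector (m3/day) for one month.
well_sink_vector <- function(site, geom, rates) {
  q <- numeric(geom$N)
  for (w in site$wells) {
    rate <- rates[[w$id]]
    if (is.null(rate) || is.na(rate) || rate == 0) next
    wts <- well_layer_weights(site, w)
    k <- geom$idx(w$screened_layers, w$row, w$col)
    q[k] <- q[k] + rate * wts
  }
  q
}

solve_dirichlet <- function(A, b, dir, hdir, factor = NULL) {
  free <- which(!dir)
  if (length(free) == 0L) return(list(h = hdir, factor = NULL))
  Aff <- A[free, free, drop = FALSE]
  bf <- b[free]
  if (any(dir)) bf <- bf - as.vector(A[free, which(dir), drop = FALSE] %*% hdir[dir])
  if (is.null(factor)) factor <- Matrix::Cholesky(methods::as(Aff, "symmetricMatrix"), LDL = FALSE)
  hf <- as.vector(Matrix::solve(factor, bf))
  h <- hdir
  h[free] <- hf
  list(h = h, factor = factor)
}

# ---- public API -------------------------------------------------------------

#' Steady predevelopment groundwater flow
#'
#' Solves the steady confined-flow finite-difference equations (7-point
#' stencil, harmonic-mean intercell conductances, head-dependent stream
#' leakage at fixed stage) on a site with no pumping: the predevelopment
#' state used as the transient initial condition and for head calibration.
#'
#' @param site A [site_model()].
#' @return A `head_field`: list with `heads` (list of one `nlay x nrow x ncol`
#'   array), `months` (`NULL` for steady), and `budget` (data.frame of
#'   in/out totals in m3/day by component plus the relative discrepancy).
#' @export
solve_steady_flow <- function(site) {
  geom <- flow_geometry(site)
  sys <- flow_system(site, geom)
  sol <- solve_dirichlet(sys$A, sys$b, sys$dir, sys$hdir)
  h <- array(sol$h, dim = c(geom$nl, geom$nr, geom$nc))
  bud <- flow_budget(site, geom, sys, h_new = sol$h, h_old = NULL, dt = NULL,
                     wells_q = numeric(geom$N))
  structure(list(heads = list(h), months = NULL, budget = bud,
                 geom = geom, sys = sys),
            class = "head_field")
}

#' Transient groundwater flow under a pumping schedule
#'
#' Implicit-Euler time stepping with monthly stress periods (pumping rates
#' constant within a month), each subdivided into `substeps_per_month` equal
#' steps.  Storage uses specific storage times cell thickness (confined).
#' Pumping at a multi-layer well is apportioned across its screened layers by
#' layer-transmissivity share.
#'
#' @param site A [site_model()].
#' @param schedule A [pumping_schedule] covering the site clock (m3/day,
#'   extraction positive).
#' @param initial A `head_field` from [solve_steady_flow()] (initial heads).
#' @param substeps_per_month Integer >= 1.
#' @return A `head_field` with one end-of-month head array per clock month
#'   and a per-month budget table.
#' @export
solve_transient_flow <- function(site, schedule, initial,
                                 substeps_per_month = 1L) {
  months <- site_clock(site)
  miss <- setdiff(unclass(months), unclass(schedule_months(schedule)))
  if (length(miss) > 0L)
    stop("solve_transient_flow: schedule does not cover clock month ",
         format(new_month_index(miss[1L])))
  geom <- initial$geom %||% flow_geometry(site)
  sys <- initial$sys %||% flow_system(site, geom)
  Scell <- rep(geom$cell_storage, times = geom$nr * geom$nc)  # layer-fastest
  h <- as.vector(initial$heads[[1L]])
  heads <- vector("list", length(months))
  budgets <- vector("list", length(months))
  factors <- list()  # one Cholesky per distinct substep length
  for (mi in seq_along(months)) {
    m <- months[mi]
    dt <- days_in_month(m) / substeps_per_month
    key <- sprintf("%.10g", dt)
    qw <- well_sink_vector(site, geom, schedule_rates(schedule, m))
    A_t <- sys$A + Matrix::Diagonal(geom$N, Scell / dt)
    if (is.null(factors[[key]])) {
      free <- which(!sys$dir)
      factors[[key]] <- Matrix::Cholesky(
        methods::as(A_t[free, free, drop = FALSE], "symmetricMatrix"), LDL = FALSE)
    }
    sub_buds <- vector("list", substeps_per_month)
    for (s in seq_len(substeps_per_month)) {
      h_prev <- h
      b_t <- sys$b - qw + Scell / dt * h
      sol <- solve_dirichlet(A_t, b_t, sys$dir, sys$hdir, factor = factors[[key]])
      h <- sol$h
      sub_buds[[s]] <- flow_budget(site, geom, sys, h_new = h, h_old = h_prev,
                                   dt = dt, wells_q = qw)
    }
    heads[[mi]] <- array(h, dim = c(geom$nl, geom$nr, geom$nc))
    # month budget = time-mean of the (exactly closed) substep budgets
    bud <- sub_buds[[1L]]
    num <- vapply(bud, is.numeric, TRUE)
    for (col in names(bud)[num])
      bud[[col]] <- mean(vapply(sub_buds, function(b) b[[col]], 1.0))
    bud$discrepancy <- max(vapply(sub_buds, function(b) b$discrepancy, 1.0))
    budgets[[mi]] <- bud
  }
  budget <- do.call(rbind, budgets)
  budget$month <- format(months)
  structure(list(heads = heads, months = months, budget = budget,
                 geom = geom, sys = sys),
            class = "head_field")
}

# Volumetric budget for one solved period, m3/day.  For transient periods the
# storage term uses the month-mean rate S * (h_old - h_new) / dt.
flow_budget <- function(site, geom, sys, h_new, h_old, dt, wells_q) {
  h <- as.vector(h_new)
  fl <- face_flows(geom, h)
  div <- face_divergence(geom, fl)        # net face inflow per cell, m3/day
  st <- site$stream_cells
  qs <- numeric(geom$N)
  if (nrow(st) > 0L) {
    k <- geom$idx(st$layer, st$row, st$col)
    qs[k] <- st$conductance * (st$stage - h[k])
  }
  rech <- numeric(geom$N)
  rc <- expand.grid(r = seq_len(geom$nr), c = seq_len(geom$nc))
  rech[geom$idx(1L, rc$r, rc$c)] <- site$recharge[cbind(rc$r, rc$c)] * geom$cell_area
  stor <- numeric(geom$N)
  if (!is.null(h_old)) {
    Scell <- rep(geom$cell_storage, times = geom$nr * geom$nc)
    stor <- Scell * (as.vector(h_old) - h) / dt   # release (+) adds water
  }
  # boundary (constant-head) exchange closes each Dirichlet cell's balance
  qb <- numeric(geom$N)
  if (any(sys$dir)) {
    k <- which(sys$dir)
    qb[k] <- -(div[k] + qs[k] + rech[k] + stor[k] - wells_q[k])
  }
  pos <- function(x) sum(x[x > 0])
  neg <- function(x) -sum(x[x < 0])
  inflow <- c(boundary = pos(qb), stream = pos(qs), recharge = pos(rech),
              wells = 0, storage = pos(stor))
  outflow <- c(boundary = neg(qb), stream = neg(qs), recharge = neg(rech),
               wells = sum(wells_q), storage = neg(stor))
  tin <- sum(inflow); tout <- sum(outflow)
  data.frame(component = "total", inflow = tin, outflow = tout,
             discrepancy = abs(tin - tout) / max(tin, tout, .Machine$double.eps),
             in_boundary = inflow[["boundary"]], in_stream = inflow[["stream"]],
             in_recharge = inflow[["recharge"]], in_storage = inflow[["storage"]],
             out_boundary = outflow[["boundary"]], out_stream = outflow[["stream"]],
             out_wells = outflow[["wells"]], out_storage = outflow[["storage"]])
}

face_flows <- function(geom, h) {
  H <- array(h, dim = c(geom$nl, geom$nr, geom$nc))
  nl <- geom$nl; nr <- geom$nr; nc <- geom$nc
  Qx <- if (nc > 1L) {
    (H[, , -nc, drop = FALSE] - H[, , -1L, drop = FALSE]) *
      array(geom$cx_l, dim = c(nl, nr, nc - 1L))
  } else array(0, dim = c(nl, nr, 0L))
  Qy <- if (nr > 1L) {
    (H[, -nr, , drop = FALSE] - H[, -1L, , drop = FALSE]) *
      array(geom$cy_l, dim = c(nl, nr - 1L, nc))
  } else array(0, dim = c(nl, 0L, nc))
  Qz <- if (nl > 1L) {
    (H[-nl, , , drop = FALSE] - H[-1L, , , drop = FALSE]) *
      array(geom$cz_l, dim = c(nl - 1L, nr, nc))
  } else array(0, dim = c(0L, nr, nc))
  list(Qx = Qx, Qy = Qy, Qz = Qz)
}

# net inflow per cell from internal faces (positive = gaining)
face_divergence <- function(geom, fl) {
  nl <- geom$nl; nr <- geom$nr; nc <- geom$nc
  div <- array(0, dim = c(nl, nr, nc))
  if (nc > 1L) {
    div[, , -1L] <- div[, , -1L, drop = FALSE] + fl$Qx
    div[, , -nc] <- div[, , -nc, drop = FALSE] - fl$Qx
  }
  if (nr > 1L) {
    div[, -1L, ] <- div[, -1L, , drop = FALSE] + fl$Qy
    div[, -nr, ] <- div[, -nr, , drop = FALSE] - fl$Qy
  }
  if (nl > 1L) {
    div[-1L, , ] <- div[-1L, , , drop = FALSE] + fl$Qz
    div[-nl, , ] <- div[-nl, , , drop = FALSE] - fl$Qz
  }
  as.vector(div)
}

#' Face-by-face Darcy flows for a solved head field
#'
#' Computes the intercell face flows and the per-cell external inflow
#' (recharge, stream gain, constant-head gain) and outflow (wells, stream
#' loss, constant-head loss) that the transport stage advects with.  One
#' entry per stress period.
#'
#' @param site A [site_model()].
#' @param heads A `head_field` solved on this site.
#' @param schedule Optional [pumping_schedule] (needed when `heads` is
#'   transient so well sinks are included).
#' @return A `cell_flow_field`: list with `periods` (list of per-period flow
#'   sets `Qx`, `Qy`, `Qz` face arrays plus `ext_in`, `ext_out` cell arrays,
#'   all m3/day), `months`, and `geom`.
#' @export
cell_flows <- function(site, heads, schedule = NULL) {
  geom <- heads$geom %||% flow_geometry(site)
  if (length(as.vector(heads$heads[[1L]])) != geom$N)
    stop("cell_flows: heads do not match the site grid")
  sys <- heads$sys %||% flow_system(site, geom)
  months <- heads$months
  periods <- vector("list", length(heads$heads))
  for (pi in seq_along(heads$heads)) {
    h <- as.vector(heads$heads[[pi]])
    fl <- face_flows(geom, h)
    div <- face_divergence(geom, fl)
    qs <- numeric(geom$N)
    st <- site$stream_cells
    if (nrow(st) > 0L) {
      k <- geom$idx(st$layer, st$row, st$col)
      qs[k] <- st$conductance * (st$stage - h[k])
    }
    rech <- numeric(geom$N)
    rc <- expand.grid(r = seq_len(geom$nr), c = seq_len(geom$nc))
    rech[geom$idx(1L, rc$r, rc$c)] <- site$recharge[cbind(rc$r, rc$c)] * geom$cell_area
    qw <- numeric(geom$N)
    if (!is.null(schedule) && !is.null(months))
      qw <- well_sink_vector(site, geom, schedule_rates(schedule, months[pi]))
    qb <- numeric(geom$N)
    if (any(sys$dir)) {
      k <- which(sys$dir)
      qb[k] <- -(div[k] + qs[k] + rech[k] - qw[k])   # storage folded into qb for
    }                                               # transient Dirichlet cells
    ext <- qb + qs + rech
    ext_in <- pmax(ext, 0)
    ext_out <- pmax(-ext, 0) + qw
    dim(ext_in) <- dim(ext_out) <- c(geom$nl, geom$nr, geom$nc)
    periods[[pi]] <- list(Qx = fl$Qx, Qy = fl$Qy, Qz = fl$Qz,
                          ext_in = ext_in, ext_out = ext_out)
  }
  structure(list(periods = periods, months = months, geom = geom),
            class = "cell_flow_field")
}

#' Head-calibration residual report
#'
#' Residual = observed - simulated head at the matching cell and month, with
#' the fraction of residuals inside a +/- band (default 1.5 m, i.e. +/-5 ft,
#' the conventional acceptance band for regional-model head calibration).
#'
#' @param observed An observation set with `head_obs` (data.frame
#'   `layer,row,col,month,head`), as produced by [sample_observations()].
#' @param simulated A `head_field` (steady fields match any month).
#' @param band Half-width of the acceptance band, m.
#' @return A `residual_report`: data.frame of residuals plus attributes
#'   `fraction_within` and `band`.
#' @export
compute_residuals <- function(observed, simulated, band = 1.5) {
  obs <- observed$head_obs
  if (is.null(obs) || nrow(obs) == 0L)
    stop("compute_residuals: no usable head observations")
  geom <- simulated$geom
  sim <- vapply(seq_len(nrow(obs)), function(i) {
    pi <- if (is.null(simulated$months)) 1L else {
      match(unclass(as_month_index(obs$month[i])), unclass(simulated$months))
    }
    if (is.na(pi)) return(NA_real_)
    simulated$heads[[pi]][obs$layer[i], obs$row[i], obs$col[i]]
  }, 1.0)
  if (anyNA(sim))
    stop("compute_residuals: observation months outside the simulated periods")
  res <- obs
  res$simulated <- sim
  res$residual <- obs$head - sim
  frac <- mean(abs(res$residual) <= band)
  structure(res, fraction_within = frac, band = band,
            class = c("residual_report", "data.frame"))
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> %d residuals, %.1f%% within +/-%g m\n",
              nrow(x), 100 * attr(x, "fraction_within"), attr(x, "band")))
  invisible(x)
}
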