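# Dissolved-phase solute transport on a solved flow field.
#
# Scheme (operator splitting within each monthly stress period):
#   1. explicit first-order upwind advection, automatically sub-stepped so
#      the cell Courant number never exceeds 1 (monotone, no new extrema);
#   2. implicit finite-volume dispersion (longitudinal/transverse
#      decomposition plus molecular diffusion), solved by conjugate
#      gradients on the symmetric positive-definite system;
#   3. exact exponential first-order decay.
# Retardation divides the advective/dispersive time step and the decay rate
# (effective-parameter scaling).  Constant-concentration source cells are
# held at the source value while active and released after their end month.
# Monthly snapshots are the state after the final sub-step of the month: a
# value stamped "1983-11" is the state on the last day of November 1983.

#' Simulate dissolved-phase contaminant transport
#'
#' Advection-dispersion-retardation-decay transport of one contaminant on
#' the Darcy flow field, with constant-concentration sources.
#'
#' @param site A [site_model()].
#' @param flows A `cell_flow_field` from [cell_flows()] on the same site and
#'   clock (a single steady period is reused for every month).
#' @param contaminant A [contaminant_spec()].
#' @param sources List of [source_term()]s (defaults to `site$sources`).
#' @param substeps_per_month Operator-splitting sub-steps per month (each
#'   sub-step runs the advect/disperse/decay cycle once).
#' @param courant_cap Maximum allowed internal advection sub-steps per
#'   splitting step; exceeding it raises a stability error.
#' @param initial Optional initial concentration array (default all zero).
#' @return A `conc_field`: list with `conc` (list of monthly
#'   `nlay x nrow x ncol` arrays, ug/L), `months`, `contaminant`, `geom`,
#'   and `mass` (total dissolved mass per month, mg).
#' @export
solve_transport <- function(site, flows, contaminant, sources = site$sources,
                            substeps_per_month = 1L, courant_cap = 500L,
                            initial = NULL) {
  stopifnot(inherits(flows, "cell_flow_field"),
            inherits(contaminant, "contaminant_spec"))
  geom <- flows$geom
  months <- site_clock(site)
  if (!is.null(flows$months) && length(flows$periods) != length(months))
    stop("solve_transport: flow periods do not cover the site clock")
  dims <- c(geom$nl, geom$nr, geom$nc)
  Vp <- array(rep(geom$pore_volume, times = geom$nr * geom$nc), dim = dims)
  C <- if (is.null(initial)) array(0, dim = dims) else {
    stopifnot(all(dim(initial) == dims)); initial
  }
  R <- contaminant$retardation
  lam <- contaminant$decay_rate

  src_idx <- lapply(sources, function(s)
    cbind(s$cells[, "layer"], s$cells[, "row"], s$cells[, "col"]))
  src_window <- lapply(sources, function(s) c(unclass(s$start), unclass(s$end)))
  src_conc <- vapply(sources, function(s) s$concentration, 1.0)
  pin_sources <- function(C, m_serial) {
    for (si in seq_along(sources)) {
      w <- src_window[[si]]
      if (m_serial >= w[1L] && m_serial <= w[2L]) C[src_idx[[si]]] <- src_conc[si]
    }
    C
  }

  out <- vector("list", length(months))
  mass <- numeric(length(months))
  per_cached <- NULL; ops <- NULL
  for (mi in seq_along(months)) {
    m <- months[mi]
    per <- flows$periods[[if (is.null(flows$months)) 1L else mi]]
    if (!identical(per, per_cached)) {
      ops <- transport_operators(site, geom, per, contaminant)
      per_cached <- per
    }
    dt_eff <- days_in_month(m) / substeps_per_month / R
    # active constant-concentration cells this month (held fixed through
    # every sub-operation, Dirichlet-style)
    active <- which(vapply(seq_along(sources), function(si) {
      w <- src_window[[si]]; unclass(m) >= w[1L] && unclass(m) <= w[2L]
    }, TRUE))
    pin_mask <- array(FALSE, dim = dims)
    for (si in active) pin_mask[src_idx[[si]]] <- TRUE
    C <- pin_sources(C, unclass(m))
    for (s in seq_len(substeps_per_month)) {
      C <- advect_upwind(C, ops, Vp, dt_eff, courant_cap, pin_mask)
      C <- disperse_implicit(C, ops, Vp, dt_eff, pin_mask)
      if (lam > 0) {
        C <- C * exp(-lam * dt_eff)   # dt_eff already divided by R
        C <- pin_sources(C, unclass(m))
      }
    }
    if (min(C) < -1e-9)
      stop("solve_transport: scheme produced negative concentration ",
           signif(min(C), 3), " in ", format(m))
    C[C < 0] <- 0
    out[[mi]] <- C
    mass[mi] <- sum(C * Vp)   # ug/L * m3 = mg
  }
  structure(list(conc = out, months = months, contaminant = contaminant,
                 geom = geom, mass = mass),
            class = "conc_field")
}

# Precompute directional upwind fluxes and dispersive face conductances for
# one flow period.
transport_operators <- function(site, geom, per, cont) {
  dims <- c(geom$nl, geom$nr, geom$nc)
  g <- site$grid
  dz <- g$layer_thickness
  por <- site$layers$porosity
  nl <- geom$nl; nr <- geom$nr; nc <- geom$nc

  # seepage velocities at faces (m/day)
  ax_l <- g$dy * dz * por                 # open area * porosity per x-face, by layer
  ay_l <- g$dx * dz * por
  az <- g$dx * g$dy
  vx <- if (nc > 1L) per$Qx / array(ax_l, dim = c(nl, nr, nc - 1L)) else per$Qx
  vy <- if (nr > 1L) per$Qy / array(ay_l, dim = c(nl, nr - 1L, nc)) else per$Qy
  porz <- if (nl > 1L) (por[-nl] + por[-1L]) / 2 else numeric(0)
  vz <- if (nl > 1L) per$Qz / (az * array(porz, dim = c(nl - 1L, nr, nc))) else per$Qz

  # cell-centred speed components (mean of adjacent face speeds)
  centred <- function(vf, axis) {
    out <- array(0, dim = dims)
    if (length(vf) == 0L) return(out)
    if (axis == 3L && nc > 1L) {
      out[, , 1L] <- abs(vf[, , 1L]); out[, , nc] <- abs(vf[, , nc - 1L])
      if (nc > 2L) out[, , 2:(nc - 1L)] <-
          (abs(vf[, , 1:(nc - 2L), drop = FALSE]) + abs(vf[, , 2:(nc - 1L), drop = FALSE])) / 2
    } else if (axis == 2L && nr > 1L) {
      out[, 1L, ] <- abs(vf[, 1L, ]); out[, nr, ] <- abs(vf[, nr - 1L, ])
      if (nr > 2L) out[, 2:(nr - 1L), ] <-
          (abs(vf[, 1:(nr - 2L), , drop = FALSE]) + abs(vf[, 2:(nr - 1L), , drop = FALSE])) / 2
    } else if (axis == 1L && nl > 1L) {
      out[1L, , ] <- abs(vf[1L, , ]); out[nl, , ] <- abs(vf[nl - 1L, , ])
      if (nl > 2L) out[2:(nl - 1L), , ] <-
          (abs(vf[1:(nl - 2L), , , drop = FALSE]) + abs(vf[2:(nl - 1L), , , drop = FALSE])) / 2
    }
    out
  }
  sx <- centred(vx, 3L); sy <- centred(vy, 2L); sz <- centred(vz, 1L)
  aL <- cont$disp_long; aT <- cont$disp_transv; Dm <- cont$mol_diffusion

  face_mean <- function(cellfield, axis) {
    if (axis == 3L) (cellfield[, , -nc, drop = FALSE] + cellfield[, , -1L, drop = FALSE]) / 2
    else if (axis == 2L) (cellfield[, -nr, , drop = FALSE] + cellfield[, -1L, , drop = FALSE]) / 2
    else (cellfield[-nl, , , drop = FALSE] + cellfield[-1L, , , drop = FALSE]) / 2
  }
  Gx <- Gy <- Gz <- NULL
  if (nc > 1L) {
    Dx <- aL * abs(vx) + aT * face_mean(sy + sz, 3L) + Dm
    Gx <- Dx * array(ax_l, dim = c(nl, nr, nc - 1L)) / g$dx
  }
  if (nr > 1L) {
    Dy <- aL * abs(vy) + aT * face_mean(sx + sz, 2L) + Dm
    Gy <- Dy * array(ay_l, dim = c(nl, nr - 1L, nc)) / g$dy
  }
  if (nl > 1L) {
    Dz_cell <- aL * sz + aT * (sx + sy) + Dm
    # series (harmonic) combination of the two half-cell conductances
    gup <- array(rep(2 * por * az / dz, times = nr * nc), dim = dims) * Dz_cell
    Gz <- array(0, dim = c(nl - 1L, nr, nc))
    num <- gup[-nl, , , drop = FALSE] * gup[-1L, , , drop = FALSE]
    den <- gup[-nl, , , drop = FALSE] + gup[-1L, , , drop = FALSE]
    pos <- den > 0
    Gz[pos] <- num[pos] / den[pos]
  }
  list(Qxp = if (nc > 1L) pmax(per$Qx, 0), Qxn = if (nc > 1L) pmax(-per$Qx, 0),
       Qyp = if (nr > 1L) pmax(per$Qy, 0), Qyn = if (nr > 1L) pmax(-per$Qy, 0),
       Qzp = if (nl > 1L) pmax(per$Qz, 0), Qzn = if (nl > 1L) pmax(-per$Qz, 0),
       ext_in = per$ext_in, Gx = Gx, Gy = Gy, Gz = Gz,
       dims = dims)
}

# Total inflow rate per cell (faces + external clean inflow), m3/day: the
# Courant control and the C_i coefficient of the upwind update.
inflow_total <- function(ops) {
  d <- ops$dims; nl <- d[1L]; nr <- d[2L]; nc <- d[3L]
  tot <- ops$ext_in + 0
  if (nc > 1L) {
    tot[, , -1L] <- tot[, , -1L, drop = FALSE] + ops$Qxp
    tot[, , -nc] <- tot[, , -nc, drop = FALSE] + ops$Qxn
  }
  if (nr > 1L) {
    tot[, -1L, ] <- tot[, -1L, , drop = FALSE] + ops$Qyp
    tot[, -nr, ] <- tot[, -nr, , drop = FALSE] + ops$Qyn
  }
  if (nl > 1L) {
    tot[-1L, , ] <- tot[-1L, , , drop = FALSE] + ops$Qzp
    tot[-nl, , ] <- tot[-nl, , , drop = FALSE] + ops$Qzn
  }
  tot
}

# One splitting step of explicit upwind advection, internally sub-stepped to
# Courant <= 1.  Update form: dC_i = (dt/Vp_i) * sum_in Q_in (C_up - C_i),
# with external inflow entering at concentration 0; outflow (wells, boundary
# losses) removes water at the cell concentration and so does not change it.
advect_upwind <- function(C, ops, Vp, dt_eff, courant_cap, pin_mask = NULL) {
  d <- ops$dims; nl <- d[1L]; nr <- d[2L]; nc <- d[3L]
  alpha <- inflow_total(ops) / Vp
  amax <- max(alpha)
  if (amax * dt_eff <= 1e-15) return(C)
  nsub <- max(1L, ceiling(amax * dt_eff))
  if (nsub > courant_cap)
    stop("solve_transport: advection needs ", nsub, " Courant sub-steps ",
         "(cap ", courant_cap, "); use a coarser time resolution or larger cells")
  dtc <- dt_eff / nsub
  pinned <- if (!is.null(pin_mask) && any(pin_mask)) C[pin_mask] else NULL
  for (s in seq_len(nsub)) {
    rhs <- -ops$ext_in * C
    if (nc > 1L) {
      rhs[, , -1L] <- rhs[, , -1L, drop = FALSE] +
        ops$Qxp * (C[, , -nc, drop = FALSE] - C[, , -1L, drop = FALSE])
      rhs[, , -nc] <- rhs[, , -nc, drop = FALSE] +
        ops$Qxn * (C[, , -1L, drop = FALSE] - C[, , -nc, drop = FALSE])
    }
    if (nr > 1L) {
      rhs[, -1L, ] <- rhs[, -1L, , drop = FALSE] +
        ops$Qyp * (C[, -nr, , drop = FALSE] - C[, -1L, , drop = FALSE])
      rhs[, -nr, ] <- rhs[, -nr, , drop = FALSE] +
        ops$Qyn * (C[, -1L, , drop = FALSE] - C[, -nr, , drop = FALSE])
    }
    if (nl > 1L) {
      rhs[-1L, , ] <- rhs[-1L, , , drop = FALSE] +
        ops$Qzp * (C[-nl, , , drop = FALSE] - C[-1L, , , drop = FALSE])
      rhs[-nl, , ] <- rhs[-nl, , , drop = FALSE] +
        ops$Qzn * (C[-1L, , , drop = FALSE] - C[-nl, , , drop = FALSE])
    }
    C <- C + dtc * rhs / Vp
    if (!is.null(pinned)) C[pin_mask] <- pinned
  }
  C
}

# Dispersive Laplacian applied to a field: (L C)_i = sum_faces G (C_nb - C_i)
dispersion_apply <- function(C, ops) {
  d <- ops$dims; nl <- d[1L]; nr <- d[2L]; nc <- d[3L]
  out <- array(0, dim = d)
  if (!is.null(ops$Gx) && nc > 1L) {
    dfx <- ops$Gx * (C[, , -1L, drop = FALSE] - C[, , -nc, drop = FALSE])
    out[, , -nc] <- out[, , -nc, drop = FALSE] + dfx
    out[, , -1L] <- out[, , -1L, drop = FALSE] - dfx
  }
  if (!is.null(ops$Gy) && nr > 1L) {
    dfy <- ops$Gy * (C[, -1L, , drop = FALSE] - C[, -nr, , drop = FALSE])
    out[, -nr, ] <- out[, -nr, , drop = FALSE] + dfy
    out[, -1L, ] <- out[, -1L, , drop = FALSE] - dfy
  }
  if (!is.null(ops$Gz) && nl > 1L) {
    dfz <- ops$Gz * (C[-1L, , , drop = FALSE] - C[-nl, , , drop = FALSE])
    out[-nl, , ] <- out[-nl, , , drop = FALSE] + dfz
    out[-1L, , ] <- out[-1L, , , drop = FALSE] - dfz
  }
  out
}

# Backward-Euler dispersion: solve (diag(Vp) + dt*Glap) C_new = Vp*C_old by
# conjugate gradients (the system is symmetric positive definite; Jacobi
# preconditioning keeps iteration counts low on graded conductances).
# Constant-concentration cells are Dirichlet conditions: eliminated from the
# free system, their (known) values feeding the right-hand side.
disperse_implicit <- function(C, ops, Vp, dt_eff, pin_mask = NULL,
                              tol = 1e-10, maxit = 2000L) {
  pin <- !is.null(pin_mask) && any(pin_mask)
  zero_pinned <- function(X) { if (pin) X[pin_mask] <- 0; X }
  matvec <- function(X) zero_pinned(Vp * X - dt_eff * dispersion_apply(X, ops))
  b <- Vp * C
  if (pin) {
    Xs <- C * 0
    Xs[pin_mask] <- C[pin_mask]
    b <- b - (Vp * Xs - dt_eff * dispersion_apply(Xs, ops))
    b <- zero_pinned(b)
  }
  x <- zero_pinned(C)
  r <- b - matvec(x)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) {
    out <- C * 0
    if (pin) out[pin_mask] <- C[pin_mask]
    return(out)
  }
  Minv <- 1 / Vp
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    if (sqrt(sum(r * r)) <= tol * bnorm) break
    Ap <- matvec(p)
    a <- rz / sum(p * Ap)
    x <- x + a * p
    r <- r - a * Ap
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (pin) x[pin_mask] <- C[pin_mask]
  x
}

#' Flow-weighted monthly well concentrations
#'
#' For each pumping month, the well concentration is the
#' transmissivity-share weighted mean over the well's screened layers at its
#' cell — the same fixed weights the flow solver uses to apportion pumping,
#' so extraction and flow agree.  Months with zero pumping are missing
#' (`NA`), never zero.
#'
#' @param conc A `conc_field` from [solve_transport()].
#' @param site The [site_model()].
#' @param schedule The [pumping_schedule()].
#' @return A named list of [monthly_series], one per well (class
#'   `well_conc_series`).
#' @export
extract_well_series <- function(conc, site, schedule) {
  months <- conc$months
  out <- list()
  aq <- which(site$grid$layer_role == "aquifer")
  for (w in site$wells) {
    if (!all(w$screened_layers %in% aq))
      stop("extract_well_series: well '", w$id, "' screened only in aquitard layers")
    wts <- well_layer_weights(site, w)
    vals <- vapply(seq_along(months), function(mi) {
      r <- schedule_rates(schedule, months[mi])[[w$id]]
      if (is.null(r) || is.na(r) || r == 0) return(NA_real_)
      sum(wts * conc$conc[[mi]][w$screened_layers, w$row, w$col])
    }, 1.0)
    out[[w$id]] <- monthly_series(months[1L], vals)
  }
  structure(out, class = "well_conc_series")
}
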