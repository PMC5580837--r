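# Extended-period simulation of the receiving water-distribution network
# during interconnection events: demand-driven hydraulics (nodal continuity
# + Hazen-Williams head loss, solved by the global gradient algorithm) and
# Lagrangian plug-flow water-quality transport (ordered parcel queues in
# links, complete instantaneous mixing at nodes, no decay — VOC loss over
# the hours-to-days of an event is negligible).  The contaminated upstream
# system is abstracted as one fixed-head, fixed-concentration reservoir.

#' Pipe network description
#'
#' @param nodes data.frame: `id`, `elev` (m), `demand` (base demand,
#'   m3/day), `area` (service-area label), `type` (`junction` or
#'   `reservoir`), `head` (fixed head, reservoirs only).
#' @param links data.frame: `id`, `from`, `to`, `type`
#'   (`pipe`/`pump`/`valve`), `length` (m), `diameter` (m), `roughness`
#'   (Hazen-Williams C), `h0`/`r` (pump curve `gain = h0 - r * Q^2`, Q in
#'   m3/day), `status` (`open`/`closed`).
#' @param patterns Named list of 24 hourly demand multipliers; nodes use
#'   pattern `"default"` unless a `pattern` column says otherwise.
#' @return A validated `pipe_network`.
#' @export
pipe_network <- function(nodes, links, patterns = list(default = rep(1, 24))) {
  nodes <- as.data.frame(nodes); links <- as.data.frame(links)
  need_n <- c("id", "elev", "demand", "area", "type")
  if (!all(need_n %in% names(nodes)))
    stop("pipe_network: nodes need columns ", paste(need_n, collapse = ", "))
  if (!"head" %in% names(nodes)) nodes$head <- NA_real_
  if (!"pattern" %in% names(nodes)) nodes$pattern <- "default"
  if (anyDuplicated(nodes$id)) stop("pipe_network: duplicate node ids")
  nres <- sum(nodes$type == "reservoir")
  if (nres != 1L) stop("pipe_network: exactly one reservoir required, found ", nres)
  if (is.na(nodes$head[nodes$type == "reservoir"]))
    stop("pipe_network: the reservoir needs a fixed head")
  if (any(nodes$demand < 0)) stop("pipe_network: demands must be >= 0")
  need_l <- c("id", "from", "to", "type")
  if (!all(need_l %in% names(links)))
    stop("pipe_network: links need columns ", paste(need_l, collapse = ", "))
  for (col in c("length", "diameter", "roughness", "h0", "r"))
    if (!col %in% names(links)) links[[col]] <- NA_real_
  if (!"status" %in% names(links)) links$status <- "open"
  bad <- !(links$from %in% nodes$id) | !(links$to %in% nodes$id)
  if (any(bad)) stop("pipe_network: link '", links$id[which(bad)[1L]],
                     "' references an unknown node")
  pipes <- links$type == "pipe"
  if (any(pipes & (is.na(links$length) | links$length <= 0 |
                     is.na(links$diameter) | links$diameter <= 0)))
    stop("pipe_network: pipe lengths and diameters must be > 0")
  for (p in patterns) if (length(p) != 24L)
    stop("pipe_network: patterns must have 24 hourly multipliers")
  unknown_pat <- setdiff(unique(nodes$pattern), names(patterns))
  if (length(unknown_pat))
    stop("pipe_network: unknown demand pattern '", unknown_pat[1L], "'")
  net <- structure(list(nodes = nodes, links = links, patterns = patterns),
                   class = "pipe_network")
  # connected when every link (valves included) is open
  comp <- reachable_nodes(net, treat_closed_open = TRUE)
  if (!all(nodes$id %in% comp))
    stop("pipe_network: graph is disconnected even with all valves open")
  net
}

#' @export
print.pipe_network <- function(x, ...) {
  cat(sprintf("<pipe_network> %d nodes (%d areas), %d links\n",
              nrow(x$nodes), length(unique(x$nodes$area)), nrow(x$links)))
  invisible(x)
}

# nodes reachable from the reservoir through open links (BFS)
reachable_nodes <- function(net, treat_closed_open = FALSE) {
  lk <- net$links
  if (!treat_closed_open) lk <- lk[lk$status == "open", , drop = FALSE]
  adj <- split(c(lk$to, lk$from), c(lk$from, lk$to))
  start <- net$nodes$id[net$nodes$type == "reservoir"]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Build a network from the native list/YAML description
#'
#' @param lst List with `reservoir`, `junctions`, `pipes`, optional `pumps`,
#'   `valves`, `patterns` (see the two-system template for the layout).
#' @return A [pipe_network()].
#' @export
pipe_network_from_list <- function(lst) {
  res <- data.frame(id = lst$reservoir$id, elev = 0, demand = 0,
                    area = "boundary", type = "reservoir",
                    head = lst$reservoir$head, pattern = "default",
                    stringsAsFactors = FALSE)
  jn <- do.call(rbind, lapply(lst$junctions, function(j)
    data.frame(id = j$id, elev = j$elev, demand = j$demand,
               area = j$area %||% "default", type = "junction",
               head = NA_real_, pattern = j$pattern %||% "default",
               stringsAsFactors = FALSE)))
  mk <- function(items, type, fill) {
    if (is.null(items) || !length(items)) return(NULL)
    do.call(rbind, lapply(items, function(l)
      data.frame(id = l$id, from = l$from, to = l$to, type = type,
                 length = l$length %||% NA_real_,
                 diameter = l$diameter %||% NA_real_,
                 roughness = l$roughness %||% NA_real_,
                 h0 = l$h0 %||% NA_real_, r = l$r %||% NA_real_,
                 status = l$status %||% fill, stringsAsFactors = FALSE)))
  }
  links <- rbind(mk(lst$pipes, "pipe", "open"),
                 mk(lst$pumps, "pump", "open"),
                 mk(lst$valves, "valve", "closed"))
  pats <- lst$patterns %||% list(default = rep(1, 24))
  pats <- lapply(pats, function(p) as.numeric(unlist(p)))
  if (is.null(pats$default)) pats$default <- rep(1, 24)
  pipe_network(rbind(res, jn), links, pats)
}

#' Read a minimal EPANET-INP-dialect network file
#'
#' Supports the sections `[RESERVOIRS]`, `[JUNCTIONS]`, `[PIPES]`,
#' `[PUMPS]`, `[VALVES]`, `[DEMANDS]`, `[PATTERNS]`, `[STATUS]` (plus an
#' ignored `[TITLE]` and terminating `[END]`); any other section is
#' rejected by name.  Units in this dialect are SI: m, m3/day, pipe
#' diameters in m.  Pumps are `id node1 node2 h0 r` (gain `h0 - r Q^2`).
#'
#' @param path Path to the INP file.
#' @return A [pipe_network()].
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  supported <- c("RESERVOIRS", "JUNCTIONS", "PIPES", "PUMPS", "VALVES",
                 "DEMANDS", "PATTERNS", "STATUS", "TITLE", "END")
  section <- NA_character_
  buf <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- toupper(gsub("\\[|\\]", "", ln))
      if (!section %in% supported)
        stop("read_inp: unsupported section [", section, "]")
      next
    }
    if (is.na(section) || section %in% c("TITLE", "END")) next
    buf[[section]] <- c(buf[[section]], ln)
  }
  tok <- function(ln) strsplit(ln, "[ \t]+")[[1L]]
  res <- do.call(rbind, lapply(buf$RESERVOIRS, function(ln) {
    t <- tok(ln)
    data.frame(id = t[1L], elev = 0, demand = 0, area = "boundary",
               type = "reservoir", head = as.numeric(t[2L]),
               pattern = "default", stringsAsFactors = FALSE)
  }))
  if (is.null(res)) stop("read_inp: no [RESERVOIRS] section")
  jn <- do.call(rbind, lapply(buf$JUNCTIONS, function(ln) {
    t <- tok(ln)
    data.frame(id = t[1L], elev = as.numeric(t[2L]),
               demand = if (length(t) >= 3L) as.numeric(t[3L]) else 0,
               area = if (length(t) >= 4L) t[4L] else "default",
               type = "junction", head = NA_real_, pattern = "default",
               stringsAsFactors = FALSE)
  }))
  for (ln in buf$DEMANDS) {
    t <- tok(ln)
    jn$demand[jn$id == t[1L]] <- as.numeric(t[2L])
    if (length(t) >= 3L) jn$pattern[jn$id == t[1L]] <- t[3L]
  }
  mkl <- function(lines, type, parse) do.call(rbind, lapply(lines, parse))
  pipes <- mkl(buf$PIPES, "pipe", function(ln) {
    t <- tok(ln)
    data.frame(id = t[1L], from = t[2L], to = t[3L], type = "pipe",
               length = as.numeric(t[4L]), diameter = as.numeric(t[5L]),
               roughness = if (length(t) >= 6L) as.numeric(t[6L]) else 120,
               h0 = NA_real_, r = NA_real_, status = "open",
               stringsAsFactors = FALSE)
  })
  pumps <- mkl(buf$PUMPS, "pump", function(ln) {
    t <- tok(ln)
    data.frame(id = t[1L], from = t[2L], to = t[3L], type = "pump",
               length = NA_real_, diameter = NA_real_, roughness = NA_real_,
               h0 = as.numeric(t[4L]),
               r = if (length(t) >= 5L) as.numeric(t[5L]) else 0,
               status = "open", stringsAsFactors = FALSE)
  })
  valves <- mkl(buf$VALVES, "valve", function(ln) {
    t <- tok(ln)
    data.frame(id = t[1L], from = t[2L], to = t[3L], type = "valve",
               length = NA_real_, diameter = NA_real_, roughness = NA_real_,
               h0 = NA_real_, r = NA_real_, status = "closed",
               stringsAsFactors = FALSE)
  })
  links <- rbind(pipes, pumps, valves)
  for (ln in buf$STATUS) {
    t <- tok(ln)
    links$status[links$id == t[1L]] <- tolower(t[2L])
  }
  # pattern lines accumulate across continuations: "<id> m1 m2 ..."
  pats <- list()
  for (ln in buf$PATTERNS) {
    t <- tok(ln)
    pats[[t[1L]]] <- c(pats[[t[1L]]], as.numeric(t[-1L]))
  }
  if (is.null(pats$default)) pats$default <- rep(1, 24)
  pipe_network(rbind(res, jn), links, pats)
}

# link resistance model: head loss g(Q) and derivative, Q in m3/day.
# Hazen-Williams (SI, Q in m3/s): hf = 10.667 L Q^1.852 / (C^1.852 D^4.871)
link_loss <- function(link) {
  if (link$type == "pipe" || (link$type == "valve" && link$status == "open")) {
    L <- if (is.na(link$length)) 1 else link$length
    Dm <- if (is.na(link$diameter)) 0.5 else link$diameter
    Cc <- if (is.na(link$roughness)) 130 else link$roughness
    r <- 10.667 * L / (Cc^1.852 * Dm^4.871) / 86400^1.852
    n <- 1.852
    # linearise below Qlow so the Newton slope stays bounded near zero flow
    Qlow <- 1e-3
    slope0 <- r * Qlow^(n - 1)
    list(g = function(Q) if (abs(Q) < Qlow) slope0 * Q else
      r * sign(Q) * abs(Q)^n,
      gp = function(Q) if (abs(Q) < Qlow) slope0 else n * r * abs(Q)^(n - 1))
  } else if (link$type == "pump") {
    h0 <- link$h0; rp <- if (is.na(link$r)) 0 else link$r
    list(g = function(Q) -h0 + rp * sign(Q) * abs(Q)^2,
         gp = function(Q) pmax(2 * rp * abs(Q), 1e-8))
  } else stop("link_loss: closed link has no loss model")
}

#' Demand-driven hydraulic solution for one hour
#'
#' Global-gradient (Todini) iteration of nodal continuity with
#' Hazen-Williams losses; pumps add head along their curve
#' `gain = h0 - r Q^2`; closed links are removed.  Converged when the
#' maximum nodal imbalance is below `1e-6` of total demand.
#'
#' @param net A [pipe_network()].
#' @param hour Hour index (1--24 pattern position; wraps).
#' @param max_iter Iteration cap (error if exceeded).
#' @return List with `flows` (named, m3/day, positive from->to), `heads`
#'   (named, m), `demands` (named, m3/day at this hour), `iterations`.
#' @export
solve_hydraulics <- function(net, hour = 1L, max_iter = 200L) {
  nodes <- net$nodes
  open <- net$links[net$links$status == "open", , drop = FALSE]
  hr <- ((as.integer(hour) - 1L) %% 24L) + 1L
  mult <- vapply(nodes$pattern, function(p) net$patterns[[p]][hr], 1.0)
  dem <- nodes$demand * mult
  names(dem) <- nodes$id
  # connectivity of demand nodes through open links
  reach <- reachable_nodes(net)
  cut <- nodes$id[dem > 0 & !(nodes$id %in% reach)]
  if (length(cut))
    stop("solve_hydraulics: demand node '", cut[1L],
         "' is disconnected from the reservoir (closed valves?)")
  jn <- nodes$id[nodes$type == "junction" & nodes$id %in% reach]
  fixed <- setNames(nodes$head, nodes$id)
  nj <- length(jn)
  total_d <- sum(dem)
  loss <- lapply(seq_len(nrow(open)), function(i) link_loss(open[i, ]))
  nl <- nrow(open)
  Q <- rep(max(total_d, 1) / max(nl, 1L), nl)
  Q[open$type == "pump"] <- max(total_d, 1)
  H <- setNames(rep(fixed[!is.na(fixed)][1L], nj), jn)
  jidx <- function(id) match(id, jn)
  for (it in seq_len(max_iter)) {
    g <- vapply(seq_len(nl), function(i) loss[[i]]$g(Q[i]), 1.0)
    gp <- vapply(seq_len(nl), function(i) loss[[i]]$gp(Q[i]), 1.0)
    D <- 1 / gp
    A <- matrix(0, nj, nj, dimnames = list(jn, jn))
    b <- -dem[jn]
    # linearised link flow: Qnew = Q - D g(Q) + D (Hf - Ht) = corr + D (Hf - Ht)
    # continuity at junction j: sum_entering Qnew - sum_leaving Qnew = demand
    # collecting H terms on the left gives the SPD system A H = b below.
    for (i in seq_len(nl)) {
      f <- open$from[i]; t <- open$to[i]
      jf <- jidx(f); jt <- jidx(t)
      corr <- Q[i] - D[i] * g[i]
      if (!is.na(jf)) { b[jf] <- b[jf] - corr; A[jf, jf] <- A[jf, jf] + D[i] }
      if (!is.na(jt)) { b[jt] <- b[jt] + corr; A[jt, jt] <- A[jt, jt] + D[i] }
      if (!is.na(jf) && !is.na(jt)) {
        A[jf, jt] <- A[jf, jt] - D[i]; A[jt, jf] <- A[jt, jf] - D[i]
      } else if (!is.na(jf)) {
        b[jf] <- b[jf] + D[i] * fixed[t]
      } else if (!is.na(jt)) {
        b[jt] <- b[jt] + D[i] * fixed[f]
      }
    }
    Hnew <- if (nj > 0L) solve(A, b) else numeric(0)
    names(Hnew) <- jn
    headof <- function(id) ifelse(is.na(fixed[id]), Hnew[id], fixed[id])
    Qnew <- vapply(seq_len(nl), function(i) {
      dh <- headof(open$from[i]) - headof(open$to[i])
      Q[i] - D[i] * g[i] + D[i] * dh
    }, 1.0)
    H <- Hnew
    Q <- Qnew
    imbal <- node_imbalance(open, Q, dem, jn)
    if (max(abs(imbal), 0) <= 1e-6 * max(total_d, 1)) {
      flows <- setNames(Q, open$id)
      heads <- c(H, fixed[!is.na(fixed)])
      return(list(flows = flows, heads = heads[nodes$id[nodes$id %in% names(heads)]],
                  demands = dem, iterations = it))
    }
  }
  stop("solve_hydraulics: no convergence in ", max_iter,
       " iterations (residual ", signif(max(abs(imbal)), 3), " m3/day)")
}

node_imbalance <- function(open, Q, dem, jn) {
  imbal <- -dem[jn]
  for (i in seq_len(nrow(open))) {
    jf <- match(open$from[i], jn); jt <- match(open$to[i], jn)
    if (!is.na(jf)) imbal[jf] <- imbal[jf] - Q[i]
    if (!is.na(jt)) imbal[jt] <- imbal[jt] + Q[i]
  }
  imbal
}

#' Lagrangian water-quality simulation over an event
#'
#' Plug-flow transport: each link holds an ordered queue of water parcels;
#' every quality step, each link delivers the parcel volume displaced by its
#' flow to its downstream node, nodes mix their inflows instantaneously
#' (demand leaves at the mixed concentration), and each link receives a new
#' upstream parcel at its upstream node's concentration.  The reservoir is
#' held at `source_conc`; the network starts clean (all zero).
#'
#' @param net A [pipe_network()].
#' @param hydraulics List of per-step hydraulic solutions (recycled if
#'   length 1), from [solve_hydraulics()].
#' @param source_conc Reservoir concentration, ug/L.
#' @param duration Event duration, hours.
#' @param step Hydraulic/reporting step, hours.
#' @return An `eps_result`: list with `times` (h), `node_conc` (steps x
#'   nodes), `flows` (steps x links), `mass` (in / delivered / stored, mg),
#'   `net`.
#' @export
simulate_quality <- function(net, hydraulics, source_conc, duration, step = 1) {
  if (source_conc < 0) stop("simulate_quality: source_conc must be >= 0")
  nodes <- net$nodes
  open0 <- net$links[net$links$status == "open", , drop = FALSE]
  nsteps <- ceiling(duration / step)
  if (length(hydraulics) == 1L) hydraulics <- rep(hydraulics, nsteps)
  if (length(hydraulics) < nsteps)
    stop("simulate_quality: hydraulics available for ", length(hydraulics),
         " steps, need ", nsteps)
  res_id <- nodes$id[nodes$type == "reservoir"]
  is_pipe <- !is.na(open0$length) & !is.na(open0$diameter)
  link_vol <- ifelse(is_pipe, pi * (open0$diameter / 2)^2 * open0$length, 1e-6)
  # quality substep: a few substeps per shortest *pipe* travel time (pumps
  # and valves are zero-volume devices and pass water through immediately)
  qmax <- max(vapply(hydraulics[seq_len(nsteps)], function(h) max(abs(h$flows)), 1.0))
  tmin <- if (any(is_pipe)) min(link_vol[is_pipe] / pmax(qmax / 24, 1e-12)) else step
  if (step > 10 * tmin)
    warning("simulate_quality: step of ", step, " h is coarse relative to the ",
            signif(tmin, 3), " h shortest link travel time")
  dtq <- step / max(1L, ceiling(step / max(min(step, tmin / 2), 1e-3)))
  queues <- lapply(link_vol, function(v) list(vol = v, conc = 0))
  # queue representation: parallel vectors, element 1 = downstream end
  conc_node <- setNames(rep(0, nrow(nodes)), nodes$id)
  conc_node[res_id] <- source_conc
  node_conc <- matrix(0, nsteps, nrow(nodes), dimnames = list(NULL, nodes$id))
  flow_rec <- matrix(0, nsteps, nrow(open0), dimnames = list(NULL, open0$id))
  mass_in <- 0; mass_delivered <- 0
  for (si in seq_len(nsteps)) {
    hyd <- hydraulics[[si]]
    Q <- hyd$flows[open0$id]
    dem <- hyd$demands
    nq <- round(step / dtq)
    for (k in seq_len(nq)) {
      inflow_mass <- setNames(rep(0, nrow(nodes)), nodes$id)
      inflow_vol <- inflow_mass
      moved <- vector("list", nrow(open0))
      for (i in seq_len(nrow(open0))) {
        qi <- Q[i]
        if (abs(qi) < 1e-12) { moved[[i]] <- NULL; next }
        vol_move <- abs(qi) * dtq / 24
        down <- if (qi > 0) open0$to[i] else open0$from[i]
        # pull vol_move from the downstream end (element 1)
        q <- queues[[i]]
        if (qi < 0) { q$vol <- rev(q$vol); q$conc <- rev(q$conc) }
        take <- 0; mass <- 0; j <- 1L
        while (take < vol_move - 1e-12 && j <= length(q$vol)) {
          use <- min(q$vol[j], vol_move - take)
          mass <- mass + use * q$conc[j]
          q$vol[j] <- q$vol[j] - use
          take <- take + use
          if (q$vol[j] <= 1e-12) j <- j + 1L
        }
        keep <- q$vol > 1e-12
        q$vol <- q$vol[keep]; q$conc <- q$conc[keep]
        if (take < vol_move - 1e-9) {  # link shorter than one substep's slug
          up <- if (qi > 0) open0$from[i] else open0$to[i]
          mass <- mass + (vol_move - take) * conc_node[up]
        }
        if (qi < 0) { q$vol <- rev(q$vol); q$conc <- rev(q$conc) }
        queues[[i]] <- q
        moved[[i]] <- list(down = down, vol = vol_move, mass = mass)
        inflow_mass[down] <- inflow_mass[down] + mass
        inflow_vol[down] <- inflow_vol[down] + vol_move
      }
      # node mixing (reservoir pinned at the source concentration)
      mix <- inflow_vol > 1e-12
      conc_new <- conc_node
      conc_new[mix] <- inflow_mass[mix] / inflow_vol[mix]
      conc_new[res_id] <- source_conc
      # push new upstream parcels at the upstream node's mixed concentration
      for (i in seq_len(nrow(open0))) {
        if (is.null(moved[[i]])) next
        qi <- Q[i]
        up <- if (qi > 0) open0$from[i] else open0$to[i]
        q <- queues[[i]]
        if (qi < 0) { q$vol <- rev(q$vol); q$conc <- rev(q$conc) }
        nq_len <- length(q$vol)
        cu <- conc_new[up]
        if (nq_len > 0L && abs(q$conc[nq_len] - cu) <= 1e-9 * max(1, cu)) {
          q$vol[nq_len] <- q$vol[nq_len] + moved[[i]]$vol   # merge equal parcels
        } else {
          q$vol <- c(q$vol, moved[[i]]$vol)
          q$conc <- c(q$conc, cu)
        }
        if (qi < 0) { q$vol <- rev(q$vol); q$conc <- rev(q$conc) }
        queues[[i]] <- q
        if (up == res_id) mass_in <- mass_in + moved[[i]]$vol * source_conc
      }
      mass_delivered <- mass_delivered +
        sum(dem[nodes$id] * dtq / 24 * conc_new[nodes$id], na.rm = TRUE)
      conc_node <- conc_new
    }
    node_conc[si, ] <- conc_node[nodes$id]
    flow_rec[si, ] <- Q
  }
  mass_stored <- sum(vapply(queues, function(q) sum(q$vol * q$conc), 1.0))
  structure(list(times = seq_len(nsteps) * step, node_conc = node_conc,
                 flows = flow_rec, step = step,
                 mass = list(inflow = mass_in, delivered = mass_delivered,
                             stored = mass_stored),
                 net = net),
            class = "eps_result")
}

#' Demand-weighted mean concentration of a service area
#'
#' @param result An `eps_result`.
#' @param area Service-area label.
#' @param window Length-2 hours range (inclusive); default the whole run.
#' @return Mean concentration, ug/L, weighted by node base demand over the
#'   area's nodes and the window's steps.
#' @export
area_mean <- function(result, area, window = range(result$times)) {
  nodes <- result$net$nodes
  sel <- nodes$type == "junction" & nodes$area == area
  if (!any(sel))
    stop("area_mean: unknown area '", area, "' (areas: ",
         paste(setdiff(unique(nodes$area), "boundary"), collapse = ", "), ")")
  steps <- which(result$times >= window[1L] & result$times <= window[2L])
  if (!length(steps)) stop("area_mean: empty time window")
  w <- nodes$demand[sel]
  if (sum(w) == 0) w <- rep(1, sum(sel))
  conc <- result$node_conc[steps, nodes$id[sel], drop = FALSE]
  sum(colMeans(conc) * w) / sum(w)
}

#' Run one interconnection event scenario end to end
#'
#' Composes hydraulics, quality transport and area summaries for either an
#' intermittent booster-pump event (`type = "pump"`: pump on, bypass valve
#' closed) or a continuous open-valve transfer (`type = "valve"`: pump
#' removed, valve open).
#'
#' @param net A [pipe_network()].
#' @param scenario List with `type` (`"pump"` or `"valve"`).
#' @param source_conc Upstream (contaminated system) concentration, ug/L.
#' @param duration Event duration, hours.
#' @param step Hydraulic step, hours.
#' @return List with `area_means` (named, ug/L), `result` (`eps_result`).
#' @export
run_event_scenario <- function(net, scenario, source_conc, duration, step = 1) {
  if (!is.list(scenario) || is.null(scenario$type) ||
      !scenario$type %in% c("pump", "valve"))
    stop("run_event_scenario: scenario$type must be 'pump' or 'valve'")
  lk <- net$links
  if (scenario$type == "pump") {
    lk$status[lk$type == "valve"] <- "closed"
    lk$status[lk$type == "pump"] <- "open"
  } else {
    lk$status[lk$type == "valve"] <- "open"
    lk <- lk[lk$type != "pump", , drop = FALSE]
  }
  net2 <- pipe_network(net$nodes, lk, net$patterns)
  if (duration <= 0) {
    areas <- setdiff(unique(net$nodes$area[net$nodes$type == "junction"]), "boundary")
    return(list(area_means = setNames(rep(0, length(areas)), areas), result = NULL))
  }
  nsteps <- ceiling(duration / step)
  hyd <- lapply(seq_len(nsteps), function(s) solve_hydraulics(net2, hour = s))
  eps <- simulate_quality(net2, hyd, source_conc, duration, step)
  areas <- setdiff(unique(net$nodes$area[net$nodes$type == "junction"]), "boundary")
  means <- vapply(areas, function(a) area_mean(eps, a), 1.0)
  list(area_means = means, result = eps)
}
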