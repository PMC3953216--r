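#' Benefit semantics of a service flow
#'
#' @param benefit_type `"provisioning"` (carrier contact benefits users) or
#'   `"preventive"` (carrier contact harms users and sinks provide the
#'   benefit by mitigation).
#' @param rivalness `"rival"` (use depletes the carrier) or `"non_rival"`.
#' @param carrier Free-text carrier name (water, sediment, scenic quality...).
#' @param units Carrier units.
#' @return An object of class `benefit_spec`.
#' @export
benefit_spec <- function(benefit_type = c("provisioning", "preventive"),
                         rivalness = c("rival", "non_rival"),
                         carrier = "carrier", units = "") {
  structure(list(benefit_type = match.arg(benefit_type),
                 rivalness = match.arg(rivalness),
                 carrier = carrier, units = units),
            class = "benefit_spec")
}

#' Flow-routing specification
#'
#' Selects how the service carrier moves across the landscape:
#' `"d8_downslope"` (hydrologic flow over a DEM), `"line_of_sight"`
#' (informational carrier along unobstructed rays, non-rival only),
#' `"access_cost"` (beneficiaries travel to sources over a cost surface) or
#' `"global_mix"` (well-mixed global pool, e.g. atmospheric CO2).
#'
#' @param mode Router mode.
#' @param dem [raster_layer()] DEM, required for `d8_downslope` and
#'   `line_of_sight`.
#' @param max_distance Sight range in map units (`line_of_sight`).
#' @param cost [raster_layer()] traversal-cost surface (`access_cost`).
#' @param max_cost Largest cumulative cost a beneficiary can spend
#'   (`access_cost`).
#' @return An object of class `router_spec`.
#' @export
router_spec <- function(mode = c("d8_downslope", "line_of_sight",
                                 "access_cost", "global_mix"),
                        dem = NULL, max_distance = NULL,
                        cost = NULL, max_cost = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("d8_downslope", "line_of_sight") && is.null(dem))
    stop("router mode '", mode, "' requires a DEM")
  if (mode == "line_of_sight" && is.null(max_distance))
    stop("line_of_sight requires max_distance")
  if (mode == "access_cost" && (is.null(cost) || is.null(max_cost)))
    stop("access_cost requires a cost layer and max_cost")
  structure(list(mode = mode, dem = dem, max_distance = max_distance,
                 cost = cost, max_cost = max_cost),
            class = "router_spec")
}

#' A SPAN flow problem
#'
#' Bundles the three production-function surfaces with benefit semantics and
#' a router. All layers must share one [grid_spec()] and be nonnegative.
#'
#' @param source Theoretical source layer (carrier units).
#' @param sink Absorption-capacity layer (same units).
#' @param use Demand layer (same units; a presence/weight surface for
#'   non-rival benefits).
#' @param benefit A [benefit_spec()].
#' @param router A [router_spec()].
#' @return An object of class `span_problem`.
#' @export
span_problem <- function(source, sink, use, benefit, router) {
  spec <- source$spec
  for (ly in list(sink, use))
    if (!same_spec(ly$spec, spec)) stop("source/sink/use grids do not match")
  for (ly in list(source, sink, use))
    if (any(ly$values < 0, na.rm = TRUE)) stop("negative source/sink/use values")
  if (router$mode == "line_of_sight" && benefit$rivalness != "non_rival")
    stop("line_of_sight routing supports non-rival benefits only")
  structure(list(source = source, sink = sink, use = use,
                 benefit = benefit, router = router, spec = spec),
            class = "span_problem")
}

# zero-filled working copy of a layer's values (NA treated as 0 for routing)
vals0 <- function(layer) {
  v <- layer$values
  v[is.na(v)] <- 0
  v
}

#' D8 flow directions from a DEM
#'
#' Each cell points at its steepest strictly-lower 8-neighbour (largest
#' drop / distance; ties broken clockwise from East). Pits, flats and `NA`
#' cells are terminal. The resulting graph is acyclic because flow is
#' strictly downhill.
#'
#' @param dem A [raster_layer()] of elevations.
#' @return Integer matrix of directions, 0-7 clockwise from East, -1 for
#'   terminal cells.
#' @export
route_d8 <- function(dem) {
  s <- dem$spec
  z <- dem$values
  dir <- matrix(-1L, s$n_rows, s$n_cols)
  for (r in seq_len(s$n_rows)) for (c in seq_len(s$n_cols)) {
    z0 <- z[r, c]
    if (is.na(z0)) next
    best <- 0; bestk <- -1L
    for (k in 1:8) {
      rr <- r + NB8_DR[k]; cc <- c + NB8_DC[k]
      if (rr < 1 || rr > s$n_rows || cc < 1 || cc > s$n_cols) next
      zn <- z[rr, cc]
      if (is.na(zn) || zn >= z0) next
      g <- (z0 - zn) / NB8_DIST[k]
      if (g > best) { best <- g; bestk <- k - 1L }
    }
    dir[r, c] <- bestk
  }
  dir
}

#' Visibility from one observer cell
#'
#' A cell is visible when the terrain profile along the straight ray between
#' the two cell centers (linear interpolation of cell-center elevations)
#' never rises strictly above the sight line. The observer cell is always
#' visible; cells whose center lies beyond `max_distance` are 0.
#'
#' @param dem A [raster_layer()].
#' @param observer Integer vector `c(row, col)` (1-based).
#' @param max_distance Range in map units (`Inf` for unlimited).
#' @return A 0/1 [raster_layer()].
#' @export
viewshed <- function(dem, observer, max_distance = Inf) {
  s <- dem$spec
  out <- matrix(0, s$n_rows, s$n_cols)
  r0 <- observer[1]; c0 <- observer[2]
  stopifnot(r0 >= 1, r0 <= s$n_rows, c0 >= 1, c0 <= s$n_cols)
  for (r in seq_len(s$n_rows)) for (c in seq_len(s$n_cols)) {
    d <- sqrt((r - r0)^2 + (c - c0)^2) * s$cell_size
    if (d > max_distance) next
    out[r, c] <- as.numeric(los_clear(dem$values, r0, c0, r, c))
  }
  raster_layer(out, s, semantics = "viewshed", units = "0/1")
}

# bilinear interpolation of cell-center elevations at fractional (row, col)
bilinear_z <- function(z, r, c) {
  nr <- nrow(z); nc <- ncol(z)
  r <- min(max(r, 1), nr); c <- min(max(c, 1), nc)
  r1 <- floor(r); r2 <- min(r1 + 1, nr); fr <- r - r1
  c1 <- floor(c); c2 <- min(c1 + 1, nc); fc <- c - c1
  (1 - fr) * ((1 - fc) * z[r1, c1] + fc * z[r1, c2]) +
    fr * ((1 - fc) * z[r2, c1] + fc * z[r2, c2])
}

# TRUE when the sight line from (r0,c0) to (r1,c1) clears the terrain.
# The terrain profile (bilinear interpolation of cell-center elevations) is
# evaluated at 100 uniform stations along the ray; stations within half a
# cell of either endpoint belong to the endpoint cells and are excluded.
los_clear <- function(z, r0, c0, r1, c1, tol = 1e-9) {
  if (r0 == r1 && c0 == c1) return(TRUE)
  z0 <- z[r0, c0]; z1 <- z[r1, c1]
  if (is.na(z0) || is.na(z1)) return(FALSE)
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  margin <- 0.5 / len
  for (t in seq(0, 1, length.out = 100)) {
    if (t < margin || t > 1 - margin) next
    zt <- bilinear_z(z, r0 + t * (r1 - r0), c0 + t * (c1 - c0))
    if (is.na(zt)) return(FALSE)
    sight <- z0 + t * (z1 - z0)
    if (zt > sight + tol) return(FALSE)
  }
  TRUE
}

# cells crossed by the ray between two cell centers (inclusive), for flow maps
ray_cells <- function(r0, c0, r1, c1) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  n <- max(1L, ceiling(8 * len))
  t <- seq(0, 1, length.out = n + 1)
  cells <- unique(cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0))))
  cells
}

#' Least cumulative travel cost from a set of origin cells
#'
#' 8-connected least-cost distance over a nonnegative cost surface. A step
#' between adjacent cells costs the mean of the two cell costs times the
#' distance factor (1 cardinal, `sqrt(2)` diagonal) times the cell size.
#' Cells costlier to reach than `max_cost` (or unreachable) are `NA`.
#'
#' @param cost A [raster_layer()] of per-cell traversal costs (>= 0).
#' @param origins Matrix (or vector) of 1-based `(row, col)` origin cells.
#' @param max_cost Cutoff (default `Inf`).
#' @return A [raster_layer()] of cumulative costs (0 at origins).
#' @export
cost_distance <- function(cost, origins, max_cost = Inf) {
  origins <- matrix(origins, ncol = 2)
  if (nrow(origins) == 0) stop("cost_distance requires at least one origin")
  g <- cost_graph(cost)
  s <- cost$spec
  ov <- (origins[, 1] - 1) * s$n_cols + origins[, 2]
  d <- igraph::distances(g, v = ov, mode = "out")
  dmin <- apply(d, 2, min)
  dmin[!is.finite(dmin) | dmin > max_cost] <- NA_real_
  raster_layer(matrix(dmin, s$n_rows, s$n_cols, byrow = TRUE), s,
               semantics = "cost_distance", units = "cost")
}

# lattice graph over grid cells with mean-endpoint-cost edge weights
cost_graph <- function(cost) {
  s <- cost$spec
  v <- cost$values
  if (any(v < 0, na.rm = TRUE)) stop("cost layer must be nonnegative")
  nr <- s$n_rows; nc <- s$n_cols
  from <- integer(0); to <- integer(0); w <- numeric(0)
  id <- function(r, c) (r - 1) * nc + c
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    for (k in c(1, 2, 3, 8)) {  # E, SE, S, NE: each undirected pair once
      rr <- r + NB8_DR[k]; cc <- c + NB8_DC[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(v[rr, cc])) next
      from <- c(from, id(r, c)); to <- c(to, id(rr, cc))
      w <- c(w, (v[r, c] + v[rr, cc]) / 2 * NB8_DIST[k] * s$cell_size)
    }
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

# ---- pass engines -----------------------------------------------------------
# A "pass" runs the carrier with a given sink surface and returns raw maps:
# list(flow, use, sink, source, terminal_out). The possible pass zeroes the
# sinks; source attribution in the actual pass reuses the possible pass's
# per-delivery origin shares so that sink action never re-ranks attribution
# (this keeps every Table-3 map nonnegative).

span_pass_d8 <- function(src, sinkcap, demand, rival, dem, spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  dir <- route_d8(dem)
  z <- dem$values
  ord <- order(-as.vector(t(z)), seq_len(nr * nc), na.last = TRUE)
  to_rc <- function(id) c((id - 1) %/% nc + 1, (id - 1) %% nc + 1)
  through <- matrix(0, nr, nc); inflow <- matrix(0, nr, nc)
  sink_abs <- matrix(0, nr, nc); use_amt <- matrix(0, nr, nc)
  terminal <- 0
  for (id in ord) {
    rc <- to_rc(id); r <- rc[1]; c <- rc[2]
    th <- inflow[r, c] + src[r, c]
    through[r, c] <- th
    a <- min(th, sinkcap[r, c])
    sink_abs[r, c] <- a
    rem <- th - a
    if (rival) {
      u <- min(rem, demand[r, c])
      use_amt[r, c] <- u
      rem <- rem - u
    } else {
      use_amt[r, c] <- min(rem, demand[r, c])
    }
    k <- dir[r, c]
    if (k >= 0) {
      rr <- r + NB8_DR[k + 1]; cc <- c + NB8_DC[k + 1]
      inflow[rr, cc] <- inflow[rr, cc] + rem
    } else terminal <- terminal + rem
  }
  list(flow = through, use = use_amt, sink = sink_abs, terminal_out = terminal,
       dir = dir)
}

# per-origin path walk through a completed d8 pass; returns, for each origin,
# the per-use-cell amount of that origin's carrier delivered (rival) or the
# per-use-cell contact share (non-rival), as sparse triplets.
d8_attribution <- function(src, pass, rival, spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  dir <- pass$dir
  res <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (src[r, c] <= 0) next
    mass <- src[r, c]
    rr <- r; cc <- c
    shares <- NULL
    repeat {
      th <- pass$flow[rr, cc]
      if (th > 0) {
        f_sink <- (th - pass$sink[rr, cc]) / th
        arriving_after_sink <- mass * f_sink
        rem_cell <- th - pass$sink[rr, cc]
        if (rem_cell > 0 && pass$use[rr, cc] > 0) {
          ufrac <- pass$use[rr, cc] / rem_cell
          took <- arriving_after_sink * ufrac
          shares <- rbind(shares, c(rr, cc, took))
          if (rival) arriving_after_sink <- arriving_after_sink - took
        }
        mass <- arriving_after_sink
      }
      k <- dir[rr, cc]
      if (k < 0 || mass <= 0) break
      rr2 <- rr + NB8_DR[k + 1]; cc2 <- cc + NB8_DC[k + 1]
      rr <- rr2; cc <- cc2
    }
    res[[length(res) + 1]] <- list(origin = c(r, c), shares = shares)
  }
  res
}

run_d8 <- function(problem) {
  spec <- problem$spec
  src <- vals0(problem$source); snk <- vals0(problem$sink)
  dmd <- vals0(problem$use)
  rival <- problem$benefit$rivalness == "rival"
  dem <- problem$router$dem
  zero <- matrix(0, spec$n_rows, spec$n_cols)
  pp <- span_pass_d8(src, zero, dmd, rival, dem, spec)
  ap <- span_pass_d8(src, snk, dmd, rival, dem, spec)
  attr_p <- d8_attribution(src, pp, rival, spec)
  src_p <- zero; src_a <- zero
  for (tr in attr_p) {
    o <- tr$origin
    if (is.null(tr$shares)) next
    if (rival) {
      tot_p <- 0; tot_a <- 0
      for (i in seq_len(nrow(tr$shares))) {
        r <- tr$shares[i, 1]; c <- tr$shares[i, 2]; amt <- tr$shares[i, 3]
        tot_p <- tot_p + amt
        if (pp$use[r, c] > 0)
          tot_a <- tot_a + amt * ap$use[r, c] / pp$use[r, c]
      }
      src_p[o[1], o[2]] <- tot_p
      src_a[o[1], o[2]] <- tot_a
    } else {
      best_p <- 0; best_a <- 0
      for (i in seq_len(nrow(tr$shares))) {
        r <- tr$shares[i, 1]; c <- tr$shares[i, 2]; amt <- tr$shares[i, 3]
        best_p <- max(best_p, amt)
        if (pp$use[r, c] > 0)
          best_a <- max(best_a, amt * ap$use[r, c] / pp$use[r, c])
      }
      src_p[o[1], o[2]] <- best_p
      src_a[o[1], o[2]] <- best_a
    }
  }
  list(possible = list(flow = pp$flow, use = pp$use, sink = pp$sink,
                       source = src_p, terminal_out = pp$terminal_out),
       actual = list(flow = ap$flow, use = ap$use, sink = ap$sink,
                     source = src_a, terminal_out = ap$terminal_out))
}

run_los <- function(problem) {
  spec <- problem$spec
  src <- vals0(problem$source); snk <- vals0(problem$sink)
  dmd <- vals0(problem$use)
  z <- problem$router$dem$values
  maxd <- problem$router$max_distance
  nr <- spec$n_rows; nc <- spec$n_cols
  zero <- matrix(0, nr, nc)
  users <- which(dmd > 0, arr.ind = TRUE)
  sources <- which(src > 0, arr.ind = TRUE)
  pass <- function(with_sinks) {
    flow <- zero; use_amt <- zero; sink_abs <- zero; src_attr <- zero
    raw_gross <- list()   # per user: contributions per source
    for (ui in seq_len(nrow(users))) {
      ur <- users[ui, 1]; uc <- users[ui, 2]
      contribs <- NULL
      for (si in seq_len(nrow(sources))) {
        sr <- sources[si, 1]; sc <- sources[si, 2]
        d <- sqrt((ur - sr)^2 + (uc - sc)^2) * spec$cell_size
        if (d > maxd) next
        if (!los_clear(z, ur, uc, sr, sc)) next
        contrib <- src[sr, sc]
        absorbed <- NULL
        if (with_sinks) {
          cells <- ray_cells(sr, sc, ur, uc)
          for (i in seq_len(nrow(cells))) {
            r <- cells[i, 1]; c <- cells[i, 2]
            if ((r == sr && c == sc) || (r == ur && c == uc)) next
            a <- min(contrib, snk[r, c])
            if (a > 0) absorbed <- rbind(absorbed, c(r, c, a))
            contrib <- contrib - a
            if (contrib <= 0) break
          }
        }
        contribs <- rbind(contribs,
                          c(sr, sc, contrib, src[sr, sc]))
        if (!is.null(absorbed))
          for (i in seq_len(nrow(absorbed)))
            sink_abs[absorbed[i, 1], absorbed[i, 2]] <-
              max(sink_abs[absorbed[i, 1], absorbed[i, 2]], absorbed[i, 3])
      }
      raw_gross[[ui]] <- contribs
    }
    list(flow = flow, use = use_amt, sink = sink_abs, source = src_attr,
         contribs = raw_gross)
  }
  pp <- pass(FALSE); ap <- pass(TRUE)
  # demand caps: the rationing factor is fixed in the sink-free pass
  finish <- function(p, scale_by) {
    flow <- zero; use_amt <- zero; src_attr <- zero
    for (ui in seq_len(nrow(users))) {
      cb <- p$contribs[[ui]]
      if (is.null(cb)) next
      ur <- users[ui, 1]; uc <- users[ui, 2]
      sc_f <- scale_by[ui]
      for (i in seq_len(nrow(cb))) {
        amt <- cb[i, 3] * sc_f
        use_amt[ur, uc] <- use_amt[ur, uc] + amt
        src_attr[cb[i, 1], cb[i, 2]] <- max(src_attr[cb[i, 1], cb[i, 2]], amt)
        cells <- ray_cells(cb[i, 1], cb[i, 2], ur, uc)
        for (j in seq_len(nrow(cells)))
          flow[cells[j, 1], cells[j, 2]] <-
            flow[cells[j, 1], cells[j, 2]] + amt
      }
    }
    list(flow = flow, use = use_amt, source = src_attr)
  }
  scale <- vapply(seq_len(nrow(users)), function(ui) {
    cb <- pp$contribs[[ui]]
    if (is.null(cb)) return(1)
    tot <- sum(cb[, 3])
    d <- dmd[users[ui, 1], users[ui, 2]]
    if (tot > d && tot > 0) d / tot else 1
  }, 1)
  fp <- finish(pp, scale); fa <- finish(ap, scale)
  list(possible = list(flow = fp$flow, use = fp$use, sink = zero,
                       source = fp$source, terminal_out = 0),
       actual = list(flow = fa$flow, use = fa$use, sink = ap$sink,
                     source = fa$source, terminal_out = 0))
}

run_access <- function(problem) {
  spec <- problem$spec
  src <- vals0(problem$source); snk <- vals0(problem$sink)
  dmd <- vals0(problem$use)
  rival <- problem$benefit$rivalness == "rival"
  cost <- problem$router$cost
  max_cost <- problem$router$max_cost
  nr <- spec$n_rows; nc <- spec$n_cols
  zero <- matrix(0, nr, nc)
  g <- cost_graph(cost)
  id <- function(r, c) (r - 1) * nc + c
  users <- which(dmd > 0, arr.ind = TRUE)
  sources <- which(src > 0, arr.ind = TRUE)
  if (nrow(users) == 0 || nrow(sources) == 0) {
    return(list(possible = list(flow = zero, use = zero, sink = zero,
                                source = zero, terminal_out = 0),
                actual = list(flow = zero, use = zero, sink = zero,
                              source = zero, terminal_out = 0)))
  }
  uids <- id(users[, 1], users[, 2])
  sids <- id(sources[, 1], sources[, 2])
  dmat <- igraph::distances(g, v = uids, to = sids)
  # reachable (user, source, cost, path)
  reach <- NULL
  paths <- list()
  for (ui in seq_len(nrow(users))) for (si in seq_len(nrow(sources))) {
    d <- dmat[ui, si]
    if (!is.finite(d) || d > max_cost) next
    reach <- rbind(reach, c(ui, si, d))
  }
  if (is.null(reach)) {
    return(list(possible = list(flow = zero, use = zero, sink = zero,
                                source = zero, terminal_out = 0),
                actual = list(flow = zero, use = zero, sink = zero,
                              source = zero, terminal_out = 0)))
  }
  path_cells <- function(ui, si) {
    key <- paste(ui, si)
    if (is.null(paths[[key]])) {
      vp <- igraph::shortest_paths(g, from = uids[ui], to = sids[si],
                                   output = "vpath")$vpath[[1]]
      v <- as.integer(vp)
      paths[[key]] <<- cbind((v - 1) %/% nc + 1, (v - 1) %% nc + 1)
    }
    paths[[key]]
  }
  # gross allocation (identical for both passes: demand is depleted by the
  # claimed amount; sinks act on what is claimed)
  alloc <- NULL  # rows: ui, si, gross
  if (rival) {
    supply <- src
    unmet <- dmd
    ord <- order(reach[, 3], reach[, 1], reach[, 2])
    reach_o <- reach[ord, , drop = FALSE]
    i <- 1
    while (i <= nrow(reach_o)) {
      j <- i
      while (j < nrow(reach_o) && reach_o[j + 1, 3] - reach_o[i, 3] < 1e-9)
        j <- j + 1
      grp <- reach_o[i:j, , drop = FALSE]
      for (si in unique(grp[, 2])) {
        sr <- sources[si, 1]; sc <- sources[si, 2]
        avail <- supply[sr, sc]
        if (avail <= 0) next
        claimants <- grp[grp[, 2] == si, 1]
        um <- vapply(claimants, function(ui) unmet[users[ui, 1], users[ui, 2]], 1)
        tot_um <- sum(um)
        if (tot_um <= 0) next
        give <- min(avail, tot_um)
        for (k in seq_along(claimants)) {
          gk <- give * um[k] / tot_um
          if (gk <= 0) next
          ui <- claimants[k]
          alloc <- rbind(alloc, c(ui, si, gk))
          unmet[users[ui, 1], users[ui, 2]] <-
            unmet[users[ui, 1], users[ui, 2]] - gk
          supply[sr, sc] <- supply[sr, sc] - gk
        }
      }
      i <- j + 1
    }
  } else {
    # non-rival: every reachable source contributes fully to every reaching
    # user; the per-user demand cap is a fixed rationing factor (sink-free)
    for (k in seq_len(nrow(reach)))
      alloc <- rbind(alloc, c(reach[k, 1], reach[k, 2],
                              src[sources[reach[k, 2], 1],
                                  sources[reach[k, 2], 2]]))
    totals <- tapply(alloc[, 3], alloc[, 1], sum)
    for (k in seq_len(nrow(alloc))) {
      ui <- alloc[k, 1]
      d <- dmd[users[ui, 1], users[ui, 2]]
      tot <- totals[as.character(ui)]
      if (tot > d) alloc[k, 3] <- alloc[k, 3] * d / tot
    }
  }
  pass <- function(with_sinks) {
    flow <- zero; use_amt <- zero; sink_abs <- zero; src_attr <- zero
    sink_left <- snk
    for (k in seq_len(nrow(alloc))) {
      ui <- alloc[k, 1]; si <- alloc[k, 2]; amt <- alloc[k, 3]
      if (amt <= 0) next
      pc <- path_cells(ui, si)
      net <- amt
      if (with_sinks && nrow(pc) > 2) {
        # path runs user -> source; absorb walking source -> user
        for (i in rev(seq_len(nrow(pc)))[-1]) {
          if (i == 1) next  # user cell itself does not absorb
          r <- pc[i, 1]; c <- pc[i, 2]
          cap <- if (rival) sink_left[r, c] else snk[r, c]
          a <- min(net, cap)
          if (a > 0) {
            if (rival) {
              sink_left[r, c] <- sink_left[r, c] - a
              sink_abs[r, c] <- sink_abs[r, c] + a
            } else sink_abs[r, c] <- max(sink_abs[r, c], a)
            net <- net - a
          }
          if (net <= 0) break
        }
      }
      ur <- users[ui, 1]; uc <- users[ui, 2]
      use_amt[ur, uc] <- use_amt[ur, uc] + net
      sr <- sources[si, 1]; sc2 <- sources[si, 2]
      if (rival) src_attr[sr, sc2] <- src_attr[sr, sc2] + net
      else src_attr[sr, sc2] <- max(src_attr[sr, sc2], net)
      for (i in seq_len(nrow(pc)))
        flow[pc[i, 1], pc[i, 2]] <- flow[pc[i, 1], pc[i, 2]] + net
    }
    list(flow = flow, use = use_amt, sink = sink_abs, source = src_attr,
         terminal_out = 0)
  }
  list(possible = pass(FALSE), actual = pass(TRUE))
}

run_global_mix <- function(problem) {
  spec <- problem$spec
  src <- vals0(problem$source); snk <- vals0(problem$sink)
  dmd <- vals0(problem$use)
  n <- spec$n_rows * spec$n_cols
  zero <- matrix(0, spec$n_rows, spec$n_cols)
  tot_s <- sum(src); tot_k <- sum(snk); tot_d <- sum(dmd)
  mk <- function(pool) {
    use_amt <- if (tot_d > 0) pmin(dmd, pool * dmd / tot_d) else zero
    delivered <- sum(use_amt)
    src_attr <- if (tot_s > 0) src * delivered / tot_s else zero
    flow <- matrix(pool / n, spec$n_rows, spec$n_cols)
    list(use = use_amt, source = src_attr, flow = flow)
  }
  pool_p <- tot_s
  absorbed <- min(tot_s, tot_k)
  pool_a <- tot_s - absorbed
  sink_abs <- if (tot_k > 0) snk * absorbed / tot_k else zero
  p <- mk(pool_p); a <- mk(pool_a)
  list(possible = list(flow = p$flow, use = p$use, sink = zero,
                       source = p$source, terminal_out = pool_p - sum(p$use)),
       actual = list(flow = a$flow, use = a$use, sink = sink_abs,
                     source = a$source, terminal_out = pool_a - sum(a$use)))
}

#' Run a SPAN flow simulation
#'
#' Executes two passes — a POSSIBLE pass with all sink capacities forced to
#' zero (Table-3: "considering flows but not sinks") and an ACTUAL pass with
#' sinks active — and assembles the full output-map taxonomy via
#' [derive_output_maps()]. Within each cell sinks act on the carrier before
#' beneficiaries. For preventive benefits the same mechanics apply with
#' reversed interpretation: `actual_use` is damage received and
#' `blocked_use` is damage prevented (sinks beneficial).
#'
#' @param problem A [span_problem()].
#' @return A `span_outputs` object; see [derive_output_maps()].
#' @export
run_span <- function(problem) {
  stopifnot(inherits(problem, "span_problem"))
  raw <- switch(problem$router$mode,
    d8_downslope = run_d8(problem),
    line_of_sight = run_los(problem),
    access_cost = run_access(problem),
    global_mix = run_global_mix(problem))
  derive_output_maps(list(source = problem$source, sink = problem$sink,
                          use = problem$use),
                     raw$possible, raw$actual)
}

#' Assemble the SPAN output-map taxonomy
#'
#' Builds the full set of theoretical / possible / actual / inaccessible /
#' blocked maps from the theoretical layers and the raw results of the two
#' passes, enforcing the subtraction identities: `blocked_X = possible_X -
#' actual_X` (X in source, use, flow), `inaccessible_source/use =
#' theoretical - possible`, `inaccessible_sink = theoretical_sink -
#' actual_sink`. Negative rounding residue is clipped at `1e-9`; a violation
#' beyond that tolerance raises an internal-consistency error.
#'
#' @param theoretical List with layers `source`, `sink`, `use`.
#' @param possible_pass,actual_pass Raw pass results (matrices `flow`, `use`,
#'   `sink`, `source`, scalar `terminal_out`).
#' @return Object of class `span_outputs`: a named list of [raster_layer()]
#'   maps plus `terminal_outflow` (possible/actual carrier leaving the grid,
#'   reported separately, accounted as neither delivered nor blocked).
#' @export
derive_output_maps <- function(theoretical, possible_pass, actual_pass) {
  spec <- theoretical$source$spec
  tol <- 1e-9
  clip <- function(m, what) {
    if (any(m < -1e-6 * max(1, max(abs(m)))))
      stop("internal consistency violation in ", what, ": min = ", min(m))
    pmax(m, 0)
  }
  L <- function(m, sem) raster_layer(m, spec, semantics = sem,
                                     units = theoretical$source$units)
  th_s <- vals0(theoretical$source); th_k <- vals0(theoretical$sink)
  th_u <- vals0(theoretical$use)
  out <- list(
    theoretical_source = L(th_s, "theoretical_source"),
    theoretical_sink = L(th_k, "theoretical_sink"),
    theoretical_use = L(th_u, "theoretical_use"),
    possible_source = L(possible_pass$source, "possible_source"),
    possible_use = L(possible_pass$use, "possible_use"),
    possible_flow = L(possible_pass$flow, "possible_flow"),
    actual_source = L(actual_pass$source, "actual_source"),
    actual_sink = L(actual_pass$sink, "actual_sink"),
    actual_use = L(actual_pass$use, "actual_use"),
    actual_flow = L(actual_pass$flow, "actual_flow"),
    inaccessible_source = L(clip(th_s - possible_pass$source,
                                 "inaccessible_source"),
                            "inaccessible_source"),
    inaccessible_sink = L(clip(th_k - actual_pass$sink, "inaccessible_sink"),
                          "inaccessible_sink"),
    inaccessible_use = L(clip(th_u - possible_pass$use, "inaccessible_use"),
                         "inaccessible_use"),
    blocked_source = L(clip(possible_pass$source - actual_pass$source,
                            "blocked_source"), "blocked_source"),
    blocked_use = L(clip(possible_pass$use - actual_pass$use, "blocked_use"),
                    "blocked_use"),
    blocked_flow = L(clip(possible_pass$flow - actual_pass$flow,
                          "blocked_flow"), "blocked_flow"))
  out$terminal_outflow <- c(possible = possible_pass$terminal_out,
                            actual = actual_pass$terminal_out)
  class(out) <- "span_outputs"
  out
}

#' @export
print.span_outputs <- function(x, ...) {
  nm <- setdiff(names(x), "terminal_outflow")
  tot <- vapply(nm, function(n) layer_total(x[[n]]), 1)
  cat("span_outputs totals:\n")
  for (n in nm) cat(sprintf("  %-20s %g\n", n, tot[n]))
  cat(sprintf("  terminal outflow: possible %g, actual %g\n",
              x$terminal_outflow["possible"], x$terminal_outflow["actual"]))
  invisible(x)
}

#' Totals of every output map
#' @param outputs A `span_outputs` object.
#' @return Named numeric vector of map totals.
#' @export
span_totals <- function(outputs) {
  nm <- setdiff(names(outputs), "terminal_outflow")
  vapply(nm, function(n) layer_total(outputs[[n]]), 1)
}

# round half away from zero (locale-independent; base round() is half-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Sustainability ratio of supply to need
#'
#' `ratio = 100 * max_potential / current_need`, reported to the nearest
#' integer percent (half away from zero).
#'
#' @param current_need Total current demand (carrier units).
#' @param max_potential Largest total deliverable supply observed (carrier
#'   units).
#' @return An object of class `sweep_result` with fields `current_need`,
#'   `max_potential` and `ratio` (integer percent).
#' @export
sweep_result <- function(current_need, max_potential) {
  if (current_need <= 0) stop("undefined ratio: current need is zero")
  structure(list(current_need = current_need, max_potential = max_potential,
                 ratio = round_half_away(100 * max_potential / current_need)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("current need %g, max potential %g, ratio %d%%\n",
              x$current_need, x$max_potential, x$ratio))
  invisible(x)
}

#' Demand-sweep sustainability analysis
#'
#' Runs the flow model repeatedly with demand scaled by each multiplier
#' (multiplier 1 is inserted if absent), records the largest total
#' `actual_use` observed as the maximum deliverable potential, and reports
#' `100 * max_potential / current_need` as an integer percent, where
#' `current_need` is the total demand at multiplier 1.
#'
#' @param problem A [span_problem()].
#' @param multipliers Increasing positive demand multipliers.
#' @return A [sweep_result()] with an extra `per_multiplier` data frame.
#' @export
sustainability_sweep <- function(problem, multipliers) {
  stopifnot(length(multipliers) >= 1, all(multipliers > 0),
            !is.unsorted(multipliers))
  if (!any(abs(multipliers - 1) < 1e-12))
    multipliers <- sort(c(1, multipliers))
  need <- layer_total(problem$use)
  if (need <= 0) stop("undefined ratio: current need is zero")
  totals <- vapply(multipliers, function(m) {
    p <- problem
    p$use <- raster_layer(p$use$values * m, p$spec,
                          semantics = p$use$semantics, units = p$use$units)
    layer_total(run_span(p)$actual_use)
  }, 1)
  res <- sweep_result(need, max(totals))
  res$per_multiplier <- data.frame(multiplier = multipliers,
                                   total_actual_use = totals)
  res
}
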