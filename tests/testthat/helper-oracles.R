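# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written as brute force / enumeration, not sharing
# code paths with the package.

# ---- Bayesian networks ------------------------------------------------------

# random DAG over 2..max_nodes binary nodes, random CPTs
rand_net <- function(seed, max_nodes = 6) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  nms <- paste0("N", seq_len(n))
  nodes <- list()
  for (i in seq_len(n)) {
    parents <- if (i == 1) character() else nms[seq_len(i - 1)][
      stats::runif(i - 1) < 0.4]
    if (length(parents) > 3) parents <- parents[1:3]
    npc <- 2^length(parents)
    cpt <- matrix(stats::runif(2 * npc, 0.05, 1), nrow = 2)
    cpt <- sweep(cpt, 2, colSums(cpt), `/`)
    nodes[[nms[i]]] <- list(states = c("no", "yes"), parents = parents,
                            cpt = array(cpt, dim = c(2, rep(2, length(parents)))))
  }
  bayes_net(nodes)
}

# exact posterior by full joint enumeration over all state combinations
enum_posterior <- function(net, evidence, target) {
  nms <- names(net$nodes)
  grids <- lapply(nms, function(n) net$nodes[[n]]$states)
  names(grids) <- nms
  joint <- expand.grid(grids, stringsAsFactors = FALSE)
  p <- rep(1, nrow(joint))
  for (n in nms) {
    nd <- net$nodes[[n]]
    for (i in seq_len(nrow(joint))) {
      idx <- c(match(joint[i, n], nd$states),
               vapply(nd$parents, function(pa)
                 match(joint[i, pa], net$nodes[[pa]]$states), 1L))
      p[i] <- p[i] * nd$cpt[matrix(idx, 1)]
    }
  }
  ev <- unlist(evidence)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(ev)) keep <- keep & joint[[v]] == ev[[v]]
  p <- p[keep]; joint <- joint[keep, , drop = FALSE]
  states <- net$nodes[[target]]$states
  post <- vapply(states, function(s) sum(p[joint[[target]] == s]), 1)
  post / sum(post)
}

# ---- d8 flow ----------------------------------------------------------------

DR8 <- c(0, 1, 1, 1, 0, -1, -1, -1)
DC8 <- c(1, 1, 0, -1, -1, -1, 0, 1)
DD8 <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# exhaustive steepest strictly-lower descent (independent of route_d8)
steepest_descent <- function(z, r, c) {
  nr <- nrow(z); nc <- ncol(z)
  best <- 0; bk <- -1L
  for (k in 1:8) {
    rr <- r + DR8[k]; cc <- c + DC8[k]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    if (is.na(z[rr, cc]) || z[rr, cc] >= z[r, c]) next
    g <- (z[r, c] - z[rr, cc]) / DD8[k]
    if (g > best) { best <- g; bk <- k - 1L }
  }
  bk
}

# per-trajectory path-walking oracle: each source cell's parcel is walked
# downstream individually, depleting shared sink and demand capacities.
# Returns flow/use/sink maps and terminal outflow for one pass.
span_oracle_pass <- function(src, sinkcap, demand, rival, z) {
  nr <- nrow(src); nc <- ncol(src)
  flow <- matrix(0, nr, nc); use <- matrix(0, nr, nc)
  sink <- matrix(0, nr, nc)
  sink_left <- sinkcap
  cap_left <- demand   # rival: remaining demand; non-rival: contact capacity
  terminal <- 0
  origins <- which(src > 0, arr.ind = TRUE)
  if (nrow(origins) > 0) {
    # process origins highest-elevation first so parcels arrive in the same
    # order as a topological sweep
    origins <- origins[order(-z[origins], origins[, 1], origins[, 2]), ,
                       drop = FALSE]
  }
  for (i in seq_len(nrow(origins))) {
    r <- origins[i, 1]; c <- origins[i, 2]
    mass <- src[r, c]
    repeat {
      flow[r, c] <- flow[r, c] + mass
      a <- min(mass, sink_left[r, c])
      sink[r, c] <- sink[r, c] + a
      sink_left[r, c] <- sink_left[r, c] - a
      mass <- mass - a
      u <- min(mass, cap_left[r, c])
      use[r, c] <- use[r, c] + u
      cap_left[r, c] <- cap_left[r, c] - u
      if (rival) mass <- mass - u
      k <- steepest_descent(z, r, c)
      if (k < 0) { terminal <- terminal + mass; break }
      r <- r + DR8[k + 1]; c <- c + DC8[k + 1]
      if (mass <= 0) break
    }
  }
  list(flow = flow, use = use, sink = sink, terminal = terminal)
}

# random rival d8 problem on a small grid
rand_d8_problem <- function(seed, n = 5, rival = TRUE) {
  set.seed(seed)
  g <- grid_spec(n, n)
  z <- matrix(stats::runif(n * n, 0, 10), n, n) +
    (n - col(matrix(0, n, n))) * 2   # tilt for an outlet
  mk <- function(p, lam) matrix(ifelse(stats::runif(n * n) < p,
                                       round(stats::rexp(n * n, 1 / lam), 2),
                                       0), n, n)
  src <- mk(0.4, 5); snk <- mk(0.3, 3); dmd <- mk(0.4, 4)
  span_problem(raster_layer(src, g), raster_layer(snk, g),
               raster_layer(dmd, g),
               benefit_spec("provisioning", if (rival) "rival" else "non_rival"),
               router_spec("d8_downslope",
                           dem = raster_layer(z, g)))
}

# ---- viewshed ---------------------------------------------------------------

# dense ray-sampling visibility oracle (100 samples per ray, bilinear)
vs_oracle <- function(z, r0, c0, r1, c1) {
  if (r0 == r1 && c0 == c1) return(TRUE)
  z0 <- z[r0, c0]; z1 <- z[r1, c1]
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  margin <- 0.5 / len
  bl <- function(r, c) {
    nr <- nrow(z); nc <- ncol(z)
    r <- min(max(r, 1), nr); c <- min(max(c, 1), nc)
    rlo <- floor(r); rhi <- min(rlo + 1, nr); fr <- r - rlo
    clo <- floor(c); chi <- min(clo + 1, nc); fc <- c - clo
    (1 - fr) * ((1 - fc) * z[rlo, clo] + fc * z[rlo, chi]) +
      fr * ((1 - fc) * z[rhi, clo] + fc * z[rhi, chi])
  }
  for (t in seq(0, 1, length.out = 100)) {
    if (t < margin || t > 1 - margin) next
    zt <- bl(r0 + t * (r1 - r0), c0 + t * (c1 - c0))
    if (zt > z0 + t * (z1 - z0) + 1e-9) return(FALSE)
  }
  TRUE
}

# ---- least cost -------------------------------------------------------------

# Bellman-Ford-style relaxation over the 8-connected lattice
cost_oracle <- function(cost, origins, cell_size = 1) {
  nr <- nrow(cost); nc <- ncol(cost)
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(origins))) d[origins[i, 1], origins[i, 2]] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      for (k in 1:8) {
        rr <- r + DR8[k]; cc <- c + DC8[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        w <- (cost[r, c] + cost[rr, cc]) / 2 * DD8[k] * cell_size
        if (d[rr, cc] + w < d[r, c] - 1e-12) {
          d[r, c] <- d[rr, cc] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# ---- misc -------------------------------------------------------------------

rand_layer <- function(seed, nr = 5, nc = 5, lam = 5, g = grid_spec(nr, nc)) {
  set.seed(seed)
  raster_layer(matrix(round(stats::rexp(nr * nc, 1 / lam), 3), nr, nc), g)
}

expect_layers_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$values, b$values, tolerance = tol)
}

# light 3x3 smoothing for viewshed fixtures (keeps terrain continuous)
smooth_for_test <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    out[r, c] <- mean(m[rs, cs])
  }
  out
}
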