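#' Discrete Bayesian network
#'
#' A DAG of discrete nodes with conditional probability tables (CPTs), used
#' as a probabilistic production function: evidence about landscape drivers
#' goes in, a posterior distribution over an output class comes out.
#'
#' Each element of `nodes` is a list with:
#' \describe{
#'   \item{states}{ordered character vector of state labels}
#'   \item{parents}{character vector of parent node names (may be empty)}
#'   \item{cpt}{numeric array with `dim = c(n_states, n_states(parent1), ...)`,
#'     columns (first margin) summing to 1 for every parent configuration}
#'   \item{midpoints}{optional numeric value per state, making the node
#'     numeric (required for expected-value and Monte-Carlo use)}
#' }
#'
#' @param nodes Named list of node definitions as above.
#' @return An object of class `bayes_net`.
#' @export
bayes_net <- function(nodes) {
  stopifnot(is.list(nodes), length(names(nodes)) == length(nodes))
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    if (is.null(nd$parents)) nodes[[nm]]$parents <- character()
    nd <- nodes[[nm]]
    stopifnot(is.character(nd$states), length(nd$states) >= 1)
    for (p in nd$parents)
      if (!p %in% names(nodes)) stop("unknown parent '", p, "' of '", nm, "'")
    k <- length(nd$states)
    want_dim <- c(k, vapply(nd$parents,
                            function(p) length(nodes[[p]]$states), 1L))
    cpt <- array(nd$cpt, dim = want_dim)
    csums <- if (length(nd$parents) == 0) sum(cpt)
             else apply(cpt, seq_along(want_dim)[-1], sum)
    if (any(abs(csums - 1) > 1e-9))
      stop("CPT of '", nm, "' has a column not summing to 1")
    nodes[[nm]]$cpt <- cpt
    if (!is.null(nd$midpoints))
      stopifnot(length(nd$midpoints) == k)
  }
  net <- structure(list(nodes = nodes), class = "bayes_net")
  bn_topo_order(net)  # errors on cycles
  net
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("bayes_net with %d nodes: %s\n", length(x$nodes),
              paste(names(x$nodes), collapse = ", ")))
  invisible(x)
}

#' Topological order of a network's nodes
#' @param net A [bayes_net()].
#' @return Character vector of node names, parents before children.
#' @export
bn_topo_order <- function(net) {
  nms <- names(net$nodes)
  indeg <- vapply(nms, function(n) length(net$nodes[[n]]$parents), 1L)
  order <- character()
  avail <- nms[indeg == 0]
  remaining <- indeg
  while (length(avail) > 0) {
    n <- avail[1]; avail <- avail[-1]
    order <- c(order, n)
    for (m in nms) {
      if (n %in% net$nodes[[m]]$parents) {
        remaining[m] <- remaining[m] - 1L
        if (remaining[m] == 0L) avail <- c(avail, m)
      }
    }
  }
  if (length(order) != length(nms)) stop("bayes_net graph has a cycle")
  order
}

#' Discrete probability distribution
#'
#' @param states Ordered character state labels.
#' @param probs Nonnegative numeric vector summing to 1.
#' @param midpoints Optional numeric value per state.
#' @return An object of class `discrete_distribution`.
#' @export
discrete_distribution <- function(states, probs, midpoints = NULL) {
  stopifnot(length(states) == length(probs), all(probs >= -1e-12))
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(states = states, probs = as.numeric(probs),
                 midpoints = midpoints),
            class = "discrete_distribution")
}

# ---- factor algebra for exact inference -------------------------------------

# A factor is list(vars = chr, tab = array over the vars' states with dimnames)
bn_factor <- function(net, node) {
  nd <- net$nodes[[node]]
  vars <- c(node, nd$parents)
  dn <- lapply(vars, function(v) net$nodes[[v]]$states)
  names(dn) <- vars
  tab <- nd$cpt
  dim(tab) <- vapply(dn, length, 1L)
  dimnames(tab) <- dn
  list(vars = vars, tab = tab)
}

factor_reduce <- function(f, var, state) {
  if (!var %in% f$vars) return(f)
  idx <- lapply(f$vars, function(v) {
    if (v == var) state else TRUE
  })
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  keep <- f$vars != var
  if (!any(keep))
    return(list(vars = character(), tab = array(as.numeric(tab), dim = 1)))
  dn <- dimnames(tab)[keep]
  tab <- array(tab, dim = dim(tab)[keep], dimnames = dn)
  list(vars = f$vars[keep], tab = tab)
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0)
    return(list(vars = f2$vars, tab = f2$tab * as.numeric(f1$tab)))
  if (length(f2$vars) == 0)
    return(list(vars = f1$vars, tab = f1$tab * as.numeric(f2$tab)))
  vars <- union(f1$vars, f2$vars)
  dn <- c(dimnames(f1$tab), dimnames(f2$tab))
  dn <- dn[!duplicated(names(dn))][vars]
  dims <- vapply(dn, length, 1L)
  grid <- expand.grid(dn, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  v1 <- if (length(f1$vars) > 0)
    f1$tab[as.matrix(grid[, f1$vars, drop = FALSE])] else as.numeric(f1$tab)
  v2 <- if (length(f2$vars) > 0)
    f2$tab[as.matrix(grid[, f2$vars, drop = FALSE])] else as.numeric(f2$tab)
  list(vars = vars, tab = array(v1 * v2, dim = dims, dimnames = dn))
}

factor_marginalize <- function(f, var) {
  if (!var %in% f$vars) return(f)
  keep <- which(f$vars != var)
  if (length(keep) == 0)
    return(list(vars = character(), tab = array(sum(f$tab), dim = 1)))
  tab <- apply(f$tab, keep, sum)
  dn <- dimnames(f$tab)[keep]
  tab <- array(tab, dim = vapply(dn, length, 1L), dimnames = dn)
  list(vars = f$vars[keep], tab = tab)
}

#' Exact posterior of one node given evidence
#'
#' Computes `P(target | evidence)` by factor-product variable elimination —
#' exact for any discrete network. Evidence may include the target itself
#' (giving a point mass).
#'
#' @param net A [bayes_net()].
#' @param evidence Named character vector or list, node -> observed state.
#' @param target Name of the query node.
#' @return A [discrete_distribution()] over the target's states.
#' @export
infer_posterior <- function(net, evidence = NULL, target) {
  stopifnot(target %in% names(net$nodes))
  ev <- unlist(evidence)
  if (length(ev) > 0) {
    for (v in names(ev)) {
      if (!v %in% names(net$nodes)) stop("evidence on unknown node '", v, "'")
      if (!ev[[v]] %in% net$nodes[[v]]$states)
        stop("evidence state '", ev[[v]], "' not a state of '", v, "'")
    }
  }
  tgt <- net$nodes[[target]]
  if (target %in% names(ev)) {
    p <- as.numeric(tgt$states == ev[[target]])
    return(discrete_distribution(tgt$states, p, tgt$midpoints))
  }
  factors <- lapply(names(net$nodes), function(n) bn_factor(net, n))
  for (v in names(ev))
    factors <- lapply(factors, factor_reduce, var = v, state = ev[[v]])
  elim <- setdiff(names(net$nodes), c(target, names(ev)))
  for (v in elim) {
    has_v <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (!any(has_v)) next
    prod <- Reduce(factor_product, factors[has_v])
    factors <- c(factors[!has_v], list(factor_marginalize(prod, v)))
  }
  res <- Reduce(factor_product, factors)
  if (!identical(res$vars, target)) {
    # bring remaining factor onto target axis (constants possible)
    stopifnot(target %in% res$vars || length(res$vars) == 0)
  }
  p <- as.numeric(res$tab)
  z <- sum(p)
  if (z <= 0) stop("inconsistent evidence: zero joint probability")
  discrete_distribution(tgt$states, p / z, tgt$midpoints)
}

#' Train CPTs from complete cases
#'
#' Dirichlet-style additive smoothing: each CPT entry becomes
#' `(count + alpha) / (parent-config count + alpha * k)` where `k` is the
#' number of target states. `alpha = 0` gives maximum-likelihood frequencies;
#' a parent configuration never seen with `alpha = 0` yields a uniform row
#' and a warning.
#'
#' @param net A [bayes_net()] providing structure and state lists.
#' @param cases Data frame with one column per node; every entry a valid
#'   state label.
#' @param alpha Prior weight (>= 0), default 1.
#' @return A new [bayes_net()] with CPTs replaced by the trained estimates.
#' @export
train_cpts <- function(net, cases, alpha = 1) {
  stopifnot(alpha >= 0)
  nodes <- net$nodes
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    if (nrow(cases) > 0) {
      if (!nm %in% names(cases)) stop("cases lack a column for node '", nm, "'")
      bad <- setdiff(unique(as.character(cases[[nm]])), nd$states)
      if (length(bad) > 0)
        stop("invalid state(s) for '", nm, "': ", paste(bad, collapse = ", "))
    }
    k <- length(nd$states)
    pdims <- vapply(nd$parents, function(p) length(nodes[[p]]$states), 1L)
    cnt <- array(0, dim = c(k, pdims))
    if (nrow(cases) > 0) {
      child_idx <- match(as.character(cases[[nm]]), nd$states)
      if (length(nd$parents) == 0) {
        t0 <- tabulate(child_idx, nbins = k)
        cnt <- array(t0, dim = k)
      } else {
        pidx <- vapply(nd$parents, function(p)
          match(as.character(cases[[p]]), nodes[[p]]$states), child_idx)
        pidx <- matrix(pidx, ncol = length(nd$parents))
        idx <- cbind(child_idx, pidx)
        for (i in seq_len(nrow(idx)))
          cnt[matrix(idx[i, ], 1)] <- cnt[matrix(idx[i, ], 1)] + 1
      }
    }
    cfg <- if (length(pdims) == 0) sum(cnt)
           else apply(cnt, seq_along(pdims) + 1, sum)
    cfg_arr <- array(rep(cfg, each = k), dim = c(k, pdims))
    zero_cfg <- cfg_arr == 0 & alpha == 0
    cpt <- ifelse(zero_cfg, 1 / k,
                  (cnt + alpha) / pmax(cfg_arr + alpha * k,
                                       .Machine$double.eps))
    if (any(zero_cfg))
      warning("unseen parent configuration(s) for '", nm,
              "' with alpha = 0; set uniform")
    nodes[[nm]]$cpt <- array(cpt, dim = c(k, pdims))
  }
  bayes_net(nodes)
}

#' Per-cell posterior distributions over a grid
#'
#' A layer whose cells each carry a discrete probability distribution over a
#' shared state list — the output of [apply_bn()] and the probabilistic
#' input to Monte-Carlo propagation. Internally an `n_rows x n_cols x
#' n_states` array; an all-`NA` slice marks a nodata cell.
#'
#' @param probs 3-d array `(n_rows, n_cols, n_states)` of probabilities.
#' @param spec A [grid_spec()].
#' @param states Ordered state labels.
#' @param midpoints Optional numeric value per state.
#' @param semantics,units Concept and unit tags.
#' @return An object of class `distribution_layer`.
#' @export
distribution_layer <- function(probs, spec, states, midpoints = NULL,
                               semantics = "", units = "") {
  stopifnot(length(dim(probs)) == 3,
            dim(probs)[1] == spec$n_rows, dim(probs)[2] == spec$n_cols,
            dim(probs)[3] == length(states))
  structure(list(spec = spec, states = states, probs = probs,
                 midpoints = midpoints, semantics = semantics, units = units),
            class = "distribution_layer")
}

#' @export
print.distribution_layer <- function(x, ...) {
  cat(sprintf("distribution_layer '%s' over %d states %s\n", x$semantics,
              length(x$states), format(x$spec)))
  invisible(x)
}

#' Point-mass distribution layer from a deterministic layer
#'
#' Wraps a [raster_layer()] as a degenerate [distribution_layer()]: every
#' cell carries a point mass at its own value, recorded in the layer's
#' `point_mass` matrix. Wherever `point_mass` is non-`NA` it overrides the
#' state probabilities, so deterministic and probabilistic cells can share
#' one layer (as in the hybrid erosion model).
#'
#' @param layer A [raster_layer()].
#' @return A `distribution_layer` whose `point_mass` field carries the
#'   per-cell values.
#' @export
as_distribution_layer <- function(layer) {
  s <- layer$spec
  probs <- array(1, dim = c(s$n_rows, s$n_cols, 1))
  probs[, , 1][is.na(layer$values)] <- NA_real_
  dl <- distribution_layer(probs, s, states = "value", midpoints = 0,
                           semantics = layer$semantics, units = layer$units)
  dl$point_mass <- layer$values
  dl
}

#' Apply a Bayesian network across a grid
#'
#' For every cell, continuous evidence layers are discretized into the
#' network's states by per-node bin edges, missing (`NA`) evidence is
#' marginalized rather than imputed, and the exact posterior of `target` is
#' attached to the cell. Evidence values outside all bins are clamped to the
#' nearest edge bin.
#'
#' @param net A [bayes_net()].
#' @param evidence_layers Named list, node -> [raster_layer()]; all layers
#'   must share one [grid_spec()]. Layers of state labels (character matrices
#'   wrapped via factors) are not supported: encode classes numerically and
#'   bin them.
#' @param discretizers Named list, node -> numeric vector of bin edges
#'   (length `n_states + 1`, strictly increasing). A node whose layer already
#'   holds 1-based state indices may use `NULL` edges.
#' @param target Query node name.
#' @return A [distribution_layer()] over the target's states.
#' @export
apply_bn <- function(net, evidence_layers, discretizers = list(), target) {
  stopifnot(length(evidence_layers) >= 1)
  spec <- evidence_layers[[1]]$spec
  for (ly in evidence_layers)
    if (!same_spec(ly$spec, spec)) stop("evidence layers not aligned")
  nr <- spec$n_rows; nc <- spec$n_cols
  nodes <- names(evidence_layers)
  # per node: matrix of state indices (NA = missing)
  idx <- lapply(nodes, function(n) {
    v <- evidence_layers[[n]]$values
    edges <- discretizers[[n]]
    k <- length(net$nodes[[n]]$states)
    if (is.null(edges)) {
      out <- round(v)
      if (any(out < 1 | out > k, na.rm = TRUE))
        stop("state indices for '", n, "' out of range")
      out
    } else {
      if (any(diff(edges) <= 0)) stop("bin edges for '", n,
                                      "' not strictly increasing")
      if (length(edges) != k + 1)
        stop("need ", k + 1, " bin edges for '", n, "'")
      b <- findInterval(v, edges, rightmost.closed = TRUE)
      b[!is.na(b) & b < 1] <- 1L          # clamp below
      b[!is.na(b) & b > k] <- k           # clamp above
      matrix(b, nr, nc)
    }
  })
  names(idx) <- nodes
  k_t <- length(net$nodes[[target]]$states)
  probs <- array(NA_real_, dim = c(nr, nc, k_t))
  # memoize posteriors per unique evidence configuration
  keys <- matrix("", nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    keys[r, c] <- paste(vapply(nodes, function(n) {
      i <- idx[[n]][r, c]
      if (is.na(i)) "." else as.character(i)
    }, ""), collapse = "|")
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    key <- keys[r, c]
    if (is.null(cache[[key]])) {
      ev <- list()
      for (n in nodes) {
        i <- idx[[n]][r, c]
        if (!is.na(i)) ev[[n]] <- net$nodes[[n]]$states[i]
      }
      cache[[key]] <- infer_posterior(net, ev, target)$probs
    }
    probs[r, c, ] <- cache[[key]]
  }
  distribution_layer(probs, spec, states = net$nodes[[target]]$states,
                     midpoints = net$nodes[[target]]$midpoints,
                     semantics = target)
}

#' Value and uncertainty maps from a distribution layer
#'
#' The paired-map presentation of a probabilistic prediction. For numeric
#' layers (midpoints present) the value map is the expected value
#' `sum(p_i * m_i)` and the uncertainty map the coefficient of variation
#' `sd / |mean|` (0 when both mean and variance are 0; nodata when the mean
#' is 0 with positive variance). For categorical layers the value map is the
#' modal state index (lowest index on ties) and the uncertainty map the
#' Shannon diversity `H = -sum(p_i * ln(p_i))` (natural log, `0 ln 0 := 0`).
#'
#' @param dl A [distribution_layer()].
#' @param kind `"numeric"` or `"categorical"`.
#' @return List with elements `value` and `uncertainty`, both
#'   [raster_layer()].
#' @export
summarize_distribution <- function(dl, kind = c("numeric", "categorical")) {
  kind <- match.arg(kind)
  nr <- dl$spec$n_rows; nc <- dl$spec$n_cols
  val <- matrix(NA_real_, nr, nc); unc <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.null(dl$point_mass) && !is.na(dl$point_mass[r, c])) {
      if (kind == "numeric") {
        val[r, c] <- dl$point_mass[r, c]
        unc[r, c] <- 0
        next
      }
    }
    p <- dl$probs[r, c, ]
    if (anyNA(p)) next
    if (kind == "numeric") {
      m <- dl$midpoints
      if (is.null(m)) stop("numeric summary requires midpoints")
      mu <- sum(p * m)
      v <- sum(p * (m - mu)^2)
      val[r, c] <- mu
      unc[r, c] <- if (mu != 0) sqrt(v) / abs(mu)
                   else if (v == 0) 0 else NA_real_
    } else {
      val[r, c] <- which.max(p)  # which.max takes lowest index on ties
      pl <- p[p > 0]
      unc[r, c] <- -sum(pl * log(pl))
    }
  }
  list(value = raster_layer(val, dl$spec, semantics = dl$semantics,
                            units = dl$units),
       uncertainty = raster_layer(unc, dl$spec,
                                  semantics = paste0(dl$semantics,
                                    if (kind == "numeric") "_cv" else "_shannon"),
                                  units = ""))
}

# ---- serialization ----------------------------------------------------------

#' Write a Bayesian network to YAML
#'
#' Schema: a `nodes` map, each with `states`, optional `midpoints`,
#' `parents`, and `cpt` given as a list of rows, each row a map with `given`
#' (parent states, omitted for roots) and `p` (probabilities in state order).
#'
#' @param net A [bayes_net()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
bn_to_yaml <- function(net, path) {
  out <- list(nodes = lapply(names(net$nodes), function(nm) {
    nd <- net$nodes[[nm]]
    pstates <- lapply(nd$parents, function(p) net$nodes[[p]]$states)
    rows <- list()
    if (length(nd$parents) == 0) {
      rows[[1]] <- list(p = as.numeric(nd$cpt))
    } else {
      grid <- expand.grid(pstates, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      names(grid) <- nd$parents
      for (i in seq_len(nrow(grid))) {
        idx <- c(list(TRUE), lapply(nd$parents, function(p)
          match(grid[i, p], net$nodes[[p]]$states)))
        p <- as.numeric(do.call(`[`, c(list(nd$cpt), idx)))
        rows[[i]] <- list(given = as.list(grid[i, , drop = FALSE]), p = p)
      }
    }
    res <- list(name = nm, states = as.list(nd$states),
                parents = as.list(nd$parents), cpt = rows)
    if (!is.null(nd$midpoints)) res$midpoints <- as.numeric(nd$midpoints)
    res
  }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a Bayesian network from YAML
#' @param path Path written by [bn_to_yaml()] (or hand-authored to the same
#'   schema).
#' @return A [bayes_net()].
#' @export
bn_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  nodes <- list()
  for (nd in raw$nodes) {
    states <- unlist(nd$states)
    parents <- as.character(unlist(nd$parents))
    k <- length(states)
    # parent state lists resolved after all nodes read; collect raw first
    nodes[[nd$name]] <- list(states = states, parents = parents,
                             midpoints = if (!is.null(nd$midpoints))
                               as.numeric(unlist(nd$midpoints)) else NULL,
                             cpt_rows = nd$cpt)
  }
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    k <- length(nd$states)
    pdims <- vapply(nd$parents, function(p) length(nodes[[p]]$states), 1L)
    cpt <- array(NA_real_, dim = c(k, pdims))
    if (length(nd$parents) == 0) {
      cpt <- array(as.numeric(unlist(nd$cpt_rows[[1]]$p)), dim = k)
    } else {
      for (row in nd$cpt_rows) {
        idx <- c(list(seq_len(k)), lapply(nd$parents, function(p)
          match(row$given[[p]], nodes[[p]]$states)))
        eg <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
        cpt[eg] <- as.numeric(unlist(row$p))
      }
    }
    nodes[[nm]]$cpt <- cpt
    nodes[[nm]]$cpt_rows <- NULL
  }
  bayes_net(nodes)
}
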