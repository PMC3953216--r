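#' Synthetic-landscape specification
#'
#' Controls the fully synthetic, statistically controlled inputs used to
#' exercise every module without any external data: a smoothed random DEM,
#' a clumped land-cover field, and per-class source/sink/use intensities.
#' Every generator is a pure function of its spec and seed.
#'
#' The default landscape is a 20 x 20 grid (cell size 1) with 50-unit
#' relief smoothed three times, three cover classes (forest-like,
#' agricultural, settled) with a mean patch size of 15 cells, and
#' intensities making forest the service source, agriculture a moderate
#' user and settlement the main demand center.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell edge length in map units (default 30, a typical
#'   satellite-derived DEM resolution in meters).
#' @param relief_amplitude Standard deviation of the DEM field (0 = flat).
#' @param smoothness Number of 3x3 mean-smoothing iterations.
#' @param tilt Monotone west-to-east drop per column in elevation units
#'   (guarantees a d8 outlet when > 0).
#' @param n_classes Number of land-cover classes.
#' @param patch_size Expected patch size in cells for the region-growing
#'   clumping.
#' @param class_intensity Data frame with columns `source`, `sink`, `use`
#'   and one row per class.
#' @param bn_cases Number of training cases generated by [make_bn_cases()]
#'   defaults.
#' @param seed Mandatory integer seed.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows = 20, n_cols = 20, cell_size = 30,
                           relief_amplitude = 50,
                           smoothness = 3, tilt = 0, n_classes = 3,
                           patch_size = 15,
                           class_intensity = data.frame(
                             source = c(10, 2, 0),
                             sink = c(2, 0, 1),
                             use = c(0, 5, 10)),
                           bn_cases = 1000, seed) {
  if (missing(seed)) stop("landscape_spec requires a seed")
  stopifnot(n_rows >= 1, n_cols >= 1, n_classes >= 1,
            nrow(class_intensity) == n_classes, patch_size >= 1)
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 relief_amplitude = relief_amplitude,
                 smoothness = smoothness, tilt = tilt,
                 n_classes = n_classes, patch_size = patch_size,
                 class_intensity = class_intensity,
                 bn_cases = bn_cases, seed = as.integer(seed)),
            class = "landscape_spec")
}

smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    out[r, c] <- mean(m[rs, cs])
  }
  out
}

#' Synthetic DEM
#'
#' Seeded Gaussian white noise smoothed by iterated 3x3 neighborhood
#' averaging (dependency-free and platform-reproducible), rescaled so the
#' field's standard deviation equals `relief_amplitude`, plus an optional
#' monotone west-to-east tilt.
#'
#' @param spec A [landscape_spec()].
#' @return A [raster_layer()] of elevations.
#' @export
make_dem <- function(spec) {
  set.seed(spec$seed)
  g <- grid_spec(spec$n_rows, spec$n_cols, cell_size = spec$cell_size)
  if (spec$relief_amplitude <= 0) {
    z <- matrix(0, spec$n_rows, spec$n_cols)
  } else {
    z <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                spec$n_rows, spec$n_cols)
    for (i in seq_len(spec$smoothness)) z <- smooth3(z)
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- (z - mean(z)) / s * spec$relief_amplitude
  }
  if (spec$tilt != 0)
    z <- z + spec$tilt * (spec$n_cols - col(z))
  raster_layer(z, g, semantics = "elevation", units = "m")
}

#' Clumped synthetic land cover
#'
#' Seeded region growing: about `n_cells / patch_size` seed cells receive
#' cycling class labels; unassigned cells then repeatedly take the class of
#' a random assigned 8-neighbour until the grid is full.
#'
#' @param spec A [landscape_spec()].
#' @return A [raster_layer()] of integer class labels `1..n_classes`.
#' @export
make_landcover <- function(spec) {
  set.seed(spec$seed + 1L)
  nr <- spec$n_rows; nc <- spec$n_cols
  n <- nr * nc
  cover <- matrix(NA_real_, nr, nc)
  n_seeds <- max(spec$n_classes, round(n / spec$patch_size))
  seeds <- sample.int(n, min(n_seeds, n))
  cover[seeds] <- rep_len(seq_len(spec$n_classes), length(seeds))
  while (anyNA(cover)) {
    todo <- which(is.na(cover), arr.ind = TRUE)
    todo <- todo[sample.int(nrow(todo)), , drop = FALSE]
    progressed <- FALSE
    for (i in seq_len(nrow(todo))) {
      r <- todo[i, 1]; c <- todo[i, 2]
      nbr <- c()
      for (k in 1:8) {
        rr <- r + NB8_DR[k]; cc <- c + NB8_DC[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (!is.na(cover[rr, cc])) nbr <- c(nbr, cover[rr, cc])
      }
      if (length(nbr) > 0) {
        cover[r, c] <- nbr[sample.int(length(nbr), 1)]
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  raster_layer(cover, grid_spec(nr, nc, cell_size = spec$cell_size),
               semantics = "land_cover", units = "class")
}

#' Complete synthetic SPAN test case
#'
#' Generates a DEM (tilted so d8 routing has a guaranteed outlet), a clumped
#' land-cover field, and source/sink/use layers set to the per-class
#' intensities — so every layer total has the closed form
#' `sum(intensity[class(cell)])`, returned alongside for assertion.
#'
#' @param spec A [landscape_spec()].
#' @param benefit A [benefit_spec()].
#' @param router_mode One of the [router_spec()] modes.
#' @return List with `problem` (a [span_problem()]), `cover`, `dem`, and
#'   `expected` (named totals of the three layers).
#' @export
make_span_case <- function(spec, benefit = benefit_spec(),
                           router_mode = "d8_downslope") {
  dspec <- spec
  if (router_mode == "d8_downslope" && spec$tilt == 0)
    dspec$tilt <- max(1, spec$relief_amplitude / spec$n_cols)
  dem <- make_dem(dspec)
  cover <- make_landcover(spec)
  g <- dem$spec
  pick <- function(col) {
    v <- matrix(spec$class_intensity[[col]][cover$values],
                spec$n_rows, spec$n_cols)
    raster_layer(v, g, semantics = col, units = benefit$units)
  }
  src <- pick("source"); snk <- pick("sink"); use <- pick("use")
  router <- switch(router_mode,
    d8_downslope = router_spec("d8_downslope", dem = dem),
    line_of_sight = router_spec("line_of_sight", dem = dem,
                                max_distance = 0.5 * spec$n_cols *
                                  g$cell_size),
    access_cost = router_spec("access_cost",
                              cost = raster_layer(
                                matrix(1, spec$n_rows, spec$n_cols), g,
                                semantics = "travel_cost"),
                              max_cost = 0.5 * spec$n_cols * g$cell_size),
    global_mix = router_spec("global_mix"))
  list(problem = span_problem(src, snk, use, benefit, router),
       cover = cover, dem = dem,
       expected = c(total_source = layer_total(src),
                    total_sink = layer_total(snk),
                    total_use = layer_total(use)))
}

#' Ancestral samples from a Bayesian network
#'
#' Draws `n` complete cases by sampling each node given its parents in
#' topological order — the synthetic "trusted dataset" used to test CPT
#' training.
#'
#' @param net A [bayes_net()].
#' @param n Number of cases.
#' @param seed Integer seed.
#' @return Data frame with one column per node, entries are state labels.
#' @export
make_bn_cases <- function(net, n, seed) {
  set.seed(seed)
  ord <- bn_topo_order(net)
  out <- as.data.frame(matrix(NA_character_, n, length(ord)),
                       stringsAsFactors = FALSE)
  names(out) <- ord
  for (nm in ord) {
    nd <- net$nodes[[nm]]
    k <- length(nd$states)
    if (length(nd$parents) == 0) {
      idx <- sample.int(k, n, replace = TRUE, prob = as.numeric(nd$cpt))
    } else {
      idx <- integer(n)
      pidx <- vapply(nd$parents, function(p)
        match(out[[p]], net$nodes[[p]]$states), integer(n))
      pidx <- matrix(pidx, ncol = length(nd$parents))
      for (i in seq_len(n)) {
        probs <- do.call(`[`, c(list(nd$cpt), list(seq_len(k)),
                                as.list(pidx[i, ])))
        idx[i] <- sample.int(k, 1, prob = probs)
      }
    }
    out[[nm]] <- nd$states[idx]
  }
  out
}
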