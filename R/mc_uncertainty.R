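#' Monte-Carlo configuration
#'
#' @param n_draws Number of joint draws (>= 1).
#' @param seed Master integer seed. Per-draw streams are derived by the
#'   documented split rule `seed_i = (seed * 1000003 + i) mod (2^31 - 1)`,
#'   so draws are reproducible individually as well as jointly.
#' @param outputs_requested Character vector of `span_outputs` map names to
#'   summarize (default: all maps).
#' @param max_seconds Optional wall-clock budget; when exceeded the run
#'   aborts returning partial results flagged invalid.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_draws, seed = 1L,
                      outputs_requested = NULL, max_seconds = Inf) {
  stopifnot(n_draws >= 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 outputs_requested = outputs_requested,
                 max_seconds = max_seconds),
            class = "mc_config")
}

draw_seed <- function(seed, i) (as.numeric(seed) * 1000003 + i) %% (2^31 - 1)

#' Sample a deterministic layer from a distribution layer
#'
#' Each cell is independently set to one of its state midpoints, drawn with
#' the cell's probabilities (point-mass cells yield their value
#' deterministically). Uses the current RNG state; seed it with `set.seed()`
#' for reproducibility.
#'
#' @param dl A numeric [distribution_layer()] (midpoints present).
#' @return A [raster_layer()].
#' @export
sample_layer <- function(dl) {
  if (is.null(dl$midpoints)) stop("sample_layer requires numeric midpoints")
  nr <- dl$spec$n_rows; nc <- dl$spec$n_cols
  out <- matrix(NA_real_, nr, nc)
  k <- length(dl$states)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.null(dl$point_mass) && !is.na(dl$point_mass[r, c])) {
      out[r, c] <- dl$point_mass[r, c]
      next
    }
    p <- dl$probs[r, c, ]
    if (anyNA(p)) next
    out[r, c] <- dl$midpoints[sample.int(k, 1, prob = p)]
  }
  raster_layer(out, dl$spec, semantics = dl$semantics, units = dl$units)
}

as_dl <- function(x) {
  if (inherits(x, "distribution_layer")) x else as_distribution_layer(x)
}

#' Monte-Carlo propagation of input uncertainty through the flow model
#'
#' Draws joint realizations of the source, sink and use layers (cells
#' independent), runs [run_span()] on each, and returns per-cell mean and
#' coefficient-of-variation maps for every requested output. Deterministic
#' [raster_layer()] inputs are admitted as point masses. The Table-3
#' subtraction identities hold for every draw (they are enforced per run),
#' hence for the means by linearity.
#'
#' @param source_dl,sink_dl,use_dl [distribution_layer()] or
#'   [raster_layer()] inputs.
#' @param benefit A [benefit_spec()].
#' @param router A [router_spec()].
#' @param cfg An [mc_config()].
#' @return Named list, one element per requested output, each
#'   `list(mean = raster_layer, cv = raster_layer)`; attributes `seed`,
#'   `n_draws` and `valid` form the run log. Aborted runs carry
#'   `valid = FALSE` and the number of completed draws.
#' @export
propagate <- function(source_dl, sink_dl, use_dl, benefit, router, cfg) {
  source_dl <- as_dl(source_dl); sink_dl <- as_dl(sink_dl)
  use_dl <- as_dl(use_dl)
  spec <- source_dl$spec
  start <- Sys.time()
  sums <- list(); sqs <- list()
  wanted <- cfg$outputs_requested
  done <- 0L
  aborted <- FALSE
  for (i in seq_len(cfg$n_draws)) {
    if (difftime(Sys.time(), start, units = "secs") > cfg$max_seconds) {
      aborted <- TRUE
      warning("Monte-Carlo run exceeded its wall-clock budget after ",
              done, " draws; partial results flagged invalid")
      break
    }
    set.seed(draw_seed(cfg$seed, i))
    prob <- span_problem(sample_layer(source_dl), sample_layer(sink_dl),
                         sample_layer(use_dl), benefit, router)
    out <- run_span(prob)
    if (is.null(wanted))
      wanted <- setdiff(names(out), "terminal_outflow")
    for (nm in wanted) {
      v <- vals0(out[[nm]])
      if (is.null(sums[[nm]])) {
        sums[[nm]] <- v; sqs[[nm]] <- v^2
      } else {
        sums[[nm]] <- sums[[nm]] + v; sqs[[nm]] <- sqs[[nm]] + v^2
      }
    }
    done <- done + 1L
  }
  if (done == 0L) stop("no Monte-Carlo draws completed")
  res <- lapply(wanted, function(nm) {
    mu <- sums[[nm]] / done
    varr <- pmax(sqs[[nm]] / done - mu^2, 0)
    cv <- ifelse(mu != 0, sqrt(varr) / abs(mu),
                 ifelse(varr == 0, 0, NA_real_))
    list(mean = raster_layer(mu, spec, semantics = paste0(nm, "_mean")),
         cv = raster_layer(cv, spec, semantics = paste0(nm, "_cv")))
  })
  names(res) <- wanted
  attr(res, "seed") <- cfg$seed
  attr(res, "n_draws") <- done
  attr(res, "valid") <- !aborted
  res
}

#' Analytic variance propagation for the well-mixed router
#'
#' In the `global_mix` router, away from the caps (total sink below total
#' source, pool below total demand, almost surely), every output is linear
#' in the input cells, so means and variances propagate in closed form
#' under cell independence: the pool is `sum(S) - sum(K)` and cell `i`
#' receives `pool * d_i / sum(d)`. Demand must be deterministic here.
#'
#' @param source_dl,sink_dl Numeric [distribution_layer()] inputs (or
#'   [raster_layer()] point masses).
#' @param use Deterministic demand [raster_layer()].
#' @return List with `mean` and `cv` [raster_layer()]s of `actual_use`.
#' @export
propagate_global_mix_analytic <- function(source_dl, sink_dl, use) {
  source_dl <- as_dl(source_dl); sink_dl <- as_dl(sink_dl)
  mom <- function(dl) {
    s <- summarize_distribution(dl, "numeric")
    mu <- vals0(s$value)
    cv <- s$uncertainty$values
    varr <- (ifelse(is.na(cv), 0, cv) * abs(mu))^2
    list(mu = mu, varr = varr)
  }
  S <- mom(source_dl); K <- mom(sink_dl)
  d <- vals0(use)
  td <- sum(d)
  if (td <= 0) stop("total demand is zero")
  pool_mu <- sum(S$mu) - sum(K$mu)
  pool_var <- sum(S$varr) + sum(K$varr)
  mu <- pool_mu * d / td
  varr <- pool_var * (d / td)^2
  cv <- ifelse(mu != 0, sqrt(varr) / abs(mu), ifelse(varr == 0, 0, NA_real_))
  list(mean = raster_layer(mu, use$spec, semantics = "actual_use_mean"),
       cv = raster_layer(cv, use$spec, semantics = "actual_use_cv"))
}
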