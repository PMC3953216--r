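#' RUSLE factor stack
#'
#' The five multiplicative factors of the Revised Universal Soil Loss
#' Equation `A = R * K * LS * C * P`, each a [raster_layer()] aligned on one
#' grid: rainfall erosivity (R), soil erodibility (K), slope
#' length-steepness (LS), cover-management (C) and support practice (P).
#' Factor derivation from primary data (rainfall records, soil texture,
#' DEMs) is out of scope: factors are inputs.
#'
#' @param R,K,LS,C,P Factor layers (all values >= 0).
#' @param slope_threshold Percent slope above which RUSLE is not considered
#'   defensible and the probabilistic steep-slope model takes over
#'   (default 20).
#' @return An object of class `rusle_factors`.
#' @export
rusle_factors <- function(R, K, LS, C, P, slope_threshold = 20) {
  layers <- list(R = R, K = K, LS = LS, C = C, P = P)
  spec <- R$spec
  for (nm in names(layers)) {
    if (!same_spec(layers[[nm]]$spec, spec)) stop("factor layers not aligned")
    if (any(layers[[nm]]$values < 0, na.rm = TRUE))
      stop("negative ", nm, " factor")
  }
  stopifnot(slope_threshold > 0)
  structure(c(layers, list(slope_threshold = slope_threshold, spec = spec)),
            class = "rusle_factors")
}

#' Annual soil loss by RUSLE
#'
#' Cellwise `A = R * K * LS * C * P`, in mass per area per year (units
#' follow the R and K inputs, conventionally t/ha/yr).
#'
#' @param factors A [rusle_factors()].
#' @return A [raster_layer()] of soil loss.
#' @export
rusle <- function(factors) {
  A <- factors$R$values * factors$K$values * factors$LS$values *
    factors$C$values * factors$P$values
  raster_layer(A, factors$spec, semantics = "soil_loss", units = "t/ha/yr")
}

#' Hybrid RUSLE / probabilistic soil-loss production function
#'
#' On gentle slopes (slope <= threshold, strict ">" switches to the steep
#' model) each cell carries a point mass at its RUSLE value; on steep
#' slopes, where the empirical RUSLE relationship is not defensible, the
#' cell receives the posterior of a Bayesian-network erosion model via
#' [apply_bn()]. The result is one seamless [distribution_layer()]; cells
#' lacking both model inputs are nodata.
#'
#' @param factors A [rusle_factors()].
#' @param slope Percent-slope [raster_layer()] (e.g. from
#'   [slope_percent()]).
#' @param steep_model List with `net` (a [bayes_net()]), `evidence_layers`,
#'   `discretizers` and `target`, as for [apply_bn()]. The target node must
#'   have numeric midpoints in the same units as the RUSLE output.
#' @return A [distribution_layer()] of annual soil loss.
#' @export
hybrid_erosion <- function(factors, slope, steep_model) {
  spec <- factors$spec
  if (!same_spec(slope$spec, spec)) stop("slope layer not aligned")
  A <- rusle(factors)
  bn_dl <- apply_bn(steep_model$net, steep_model$evidence_layers,
                    steep_model$discretizers, steep_model$target)
  if (!same_spec(bn_dl$spec, spec)) stop("steep model grid not aligned")
  if (is.null(bn_dl$midpoints))
    stop("steep-model target node needs numeric midpoints")
  steep <- !is.na(slope$values) & slope$values > factors$slope_threshold
  probs <- bn_dl$probs
  pm <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  for (r in seq_len(spec$n_rows)) for (c in seq_len(spec$n_cols)) {
    if (steep[r, c]) next                 # keep BN posterior
    probs[r, c, ] <- NA_real_
    pm[r, c] <- A$values[r, c]            # RUSLE point mass (NA stays nodata)
  }
  dl <- distribution_layer(probs, spec, states = bn_dl$states,
                           midpoints = bn_dl$midpoints,
                           semantics = "soil_loss", units = "t/ha/yr")
  dl$point_mass <- pm
  dl
}

#' Sediment concentration from delivered totals
#'
#' Ratio of total sediment mass delivered per year to total water volume
#' delivered per year, in kg/m3.year — the comparative water-contamination
#' indicator used to contrast regions.
#'
#' @param sediment_delivered Total sediment delivered (kg/year).
#' @param water_delivered Total water delivered (m3/year), > 0.
#' @return Concentration (kg/m3.year).
#' @export
sediment_concentration <- function(sediment_delivered, water_delivered) {
  if (water_delivered <= 0)
    stop("undefined sediment concentration: no water delivered")
  sediment_delivered / water_delivered
}

#' Illustrative steep-slope erosion network
#'
#' A small synthetic 4-node discrete network (soil class, precipitation
#' class and vegetation cover driving an erosion class with numeric
#' midpoints in t/ha/yr), shipped so the hybrid model is runnable out of the
#' box. Its structure and CPTs are illustrative conventions for testing and
#' demonstration only — they do not represent any calibrated regional
#' model, and users are expected to replace the net with their own.
#'
#' @return A [bayes_net()] with target node `"erosion"`.
#' @export
example_erosion_bn <- function() {
  # erosion propensity rises with erodible soil, heavy rain, sparse cover
  soil_states <- c("stable", "moderate", "erodible")
  rain_states <- c("low", "medium", "high")
  veg_states <- c("dense", "open", "bare")
  ero_states <- c("slight", "moderate", "severe", "extreme")
  # CPT built from an additive risk score, then softmax-like sharpening
  cpt <- array(0, dim = c(4, 3, 3, 3))
  for (s in 1:3) for (p in 1:3) for (v in 1:3) {
    risk <- (s - 1) + (p - 1) + (v - 1)          # 0 .. 6
    center <- 1 + 3 * risk / 6                   # 1 .. 4
    w <- exp(-(seq_len(4) - center)^2)
    cpt[, s, p, v] <- w / sum(w)
  }
  bayes_net(list(
    soil = list(states = soil_states, parents = character(),
                cpt = c(0.4, 0.35, 0.25)),
    precipitation = list(states = rain_states, parents = character(),
                         cpt = c(0.3, 0.45, 0.25)),
    vegetation = list(states = veg_states, parents = character(),
                      cpt = c(0.5, 0.3, 0.2)),
    erosion = list(states = ero_states,
                   parents = c("soil", "precipitation", "vegetation"),
                   cpt = cpt,
                   midpoints = c(1, 10, 40, 120))))
}
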