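#' Candidate dataset or model record
#'
#' Metadata describing one "building block" available to observe a concept,
#' ranked by [score_candidate()] during model assembly.
#'
#' @param id Unique identifier (used for deterministic tie-breaking).
#' @param concept Tag of the concept the candidate observes.
#' @param kind `"dataset"` (leaf) or `"model"` (resolves `requires`
#'   recursively).
#' @param semantic_tags Ordered specificity path, most general first, e.g.
#'   `c("carbon", "soil-carbon", "top-soil-carbon")`. Defaults to
#'   `c(concept)`.
#' @param extent Named numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @param resolution Cell size of the candidate's native grid.
#' @param time_period Optional numeric `c(start, end)` (e.g. years).
#' @param source_ontology Tag of the ontology/project the candidate comes
#'   from.
#' @param user_rank Optional user-attributed quality rank in `[0, 100]`;
#'   50 is assumed when unspecified.
#' @param requires Concept tags a model candidate needs (models only).
#' @param context_predicates Optional character vector of guard expressions
#'   over context variables (e.g. `"slope > 20"`); an expression may
#'   evaluate to a logical scalar (eligibility) or a logical matrix
#'   (spatial segment served).
#' @param payload Optional arbitrary payload (layer path, function, ...).
#' @return An object of class `candidate_record`.
#' @export
candidate_record <- function(id, concept, kind = c("dataset", "model"),
                             semantic_tags = concept,
                             extent = c(xmin = -Inf, xmax = Inf,
                                        ymin = -Inf, ymax = Inf),
                             resolution = 1, time_period = NULL,
                             source_ontology = "default", user_rank = NULL,
                             requires = character(),
                             context_predicates = NULL, payload = NULL) {
  kind <- match.arg(kind)
  if (!is.null(user_rank))
    stopifnot(user_rank >= 0, user_rank <= 100)
  structure(list(id = id, concept = concept, kind = kind,
                 semantic_tags = semantic_tags,
                 extent = extent, resolution = resolution,
                 time_period = time_period,
                 source_ontology = source_ontology, user_rank = user_rank,
                 requires = requires,
                 context_predicates = context_predicates,
                 payload = payload, scenario_priority = FALSE),
            class = "candidate_record")
}

#' Resolution context
#'
#' The spatial/temporal frame and criterion weights against which candidates
#' are ranked.
#'
#' @param extent Named numeric `c(xmin, xmax, ymin, ymax)` of the area of
#'   interest.
#' @param cell_size Target cell size.
#' @param grid Optional [grid_spec()] (needed when predicates partition the
#'   grid spatially).
#' @param time_period Optional numeric `c(start, end)`.
#' @param variables Named list of context variables available to candidate
#'   guard expressions (scalars or [raster_layer()]s).
#' @param weights Nonnegative per-criterion weights, names among
#'   `semantic`, `scale`, `detail`, `distance`, `currency`, `user`;
#'   normalized to sum to 1. Default uniform.
#' @param ontology Context ontology tag (for the semantic-distance
#'   criterion).
#' @param target_path Optional ordered tag path of the concept being
#'   resolved (for the semantic-specificity criterion).
#' @return An object of class `resolution_context`.
#' @export
resolution_context <- function(extent = c(xmin = 0, xmax = 1, ymin = 0,
                                          ymax = 1),
                               cell_size = 1, grid = NULL,
                               time_period = NULL, variables = list(),
                               weights = NULL, ontology = "default",
                               target_path = NULL) {
  crit <- c("semantic", "scale", "detail", "distance", "currency", "user")
  if (is.null(weights)) weights <- stats::setNames(rep(1, 6), crit)
  stopifnot(all(names(weights) %in% crit), all(weights >= 0),
            sum(weights) > 0)
  w <- stats::setNames(rep(0, 6), crit)
  w[names(weights)] <- weights
  w <- w / sum(w)
  structure(list(extent = extent, cell_size = cell_size, grid = grid,
                 time_period = time_period, variables = variables,
                 weights = w, ontology = ontology,
                 target_path = target_path),
            class = "resolution_context")
}

overlap_fraction <- function(cand_extent, ctx_extent) {
  ix <- max(0, min(cand_extent["xmax"], ctx_extent["xmax"]) -
               max(cand_extent["xmin"], ctx_extent["xmin"]))
  iy <- max(0, min(cand_extent["ymax"], ctx_extent["ymax"]) -
               max(cand_extent["ymin"], ctx_extent["ymin"]))
  ax <- ctx_extent["xmax"] - ctx_extent["xmin"]
  ay <- ctx_extent["ymax"] - ctx_extent["ymin"]
  if (ax <= 0 || ay <= 0) return(1)
  inf_cand <- !all(is.finite(cand_extent))
  if (inf_cand) return(1)  # global candidate covers any finite context
  unname((ix * iy) / (ax * ay))
}

#' Score one candidate against a context
#'
#' Weighted sum of six criterion scores, each normalized to `[0, 100]`:
#' semantic specificity (depth of the matching tag path over the target
#' path depth), scale specificity (fraction of the context extent covered),
#' detail (context cell size over candidate resolution, capped at 1),
#' semantic distance (100 for the same source ontology, 50 otherwise),
#' currency (coverage of the context time period; 100 when either side
#' states none) and user rank (50 when unspecified).
#'
#' @param cand A [candidate_record()].
#' @param ctx A [resolution_context()].
#' @param target_path Ordered tag path of the requested concept (defaults
#'   to `ctx$target_path`, then to the candidate's own concept).
#' @return List with `score` (in `[0, 100]`) and named `breakdown`.
#' @export
score_candidate <- function(cand, ctx, target_path = NULL) {
  if (is.null(target_path)) target_path <- ctx$target_path
  if (is.null(target_path)) target_path <- cand$concept
  ov <- overlap_fraction(cand$extent, ctx$extent)
  if (ov <= 0) stop("candidate '", cand$id, "' does not overlap the context")
  prefix <- 0
  for (i in seq_len(min(length(target_path), length(cand$semantic_tags)))) {
    if (target_path[i] == cand$semantic_tags[i]) prefix <- i else break
  }
  b <- c(
    semantic = 100 * prefix / length(target_path),
    scale = 100 * ov,
    detail = 100 * min(1, ctx$cell_size / cand$resolution),
    distance = if (identical(cand$source_ontology, ctx$ontology)) 100 else 50,
    currency = {
      if (is.null(ctx$time_period) || is.null(cand$time_period)) 100
      else {
        lo <- max(ctx$time_period[1], cand$time_period[1])
        hi <- min(ctx$time_period[2], cand$time_period[2])
        span <- ctx$time_period[2] - ctx$time_period[1]
        if (span <= 0) 100 * as.numeric(hi >= lo)
        else 100 * max(0, hi - lo) / span
      }
    },
    user = if (is.null(cand$user_rank)) 50 else cand$user_rank)
  list(score = unname(sum(ctx$weights * b)), breakdown = b)
}

#' Rank candidates by context fit
#'
#' Candidates that do not overlap the context are excluded. Order:
#' scenario-override priority first, then descending score, then finer
#' resolution, then lexicographic id — fully deterministic so model
#' assembly is auditable.
#'
#' @param cands List of [candidate_record()].
#' @param ctx A [resolution_context()].
#' @param target_path Optional tag path of the requested concept.
#' @return The candidates in rank order, each with `score` and `breakdown`
#'   fields attached.
#' @export
rank_candidates <- function(cands, ctx, target_path = NULL) {
  keep <- Filter(function(cc) overlap_fraction(cc$extent, ctx$extent) > 0,
                 cands)
  if (length(keep) == 0) stop("no candidate overlaps the context")
  scored <- lapply(keep, function(cc) {
    s <- score_candidate(cc, ctx, target_path)
    cc$score <- s$score; cc$breakdown <- s$breakdown
    cc
  })
  prio <- vapply(scored, function(cc) cc$scenario_priority, TRUE)
  sc <- vapply(scored, function(cc) cc$score, 1)
  res <- vapply(scored, function(cc) cc$resolution, 1)
  ids <- vapply(scored, function(cc) cc$id, "")
  scored[order(-as.numeric(prio), -sc, res, ids)]
}

eval_predicates <- function(cand, ctx) {
  # returns TRUE, FALSE, or a logical matrix over the ctx grid
  if (is.null(cand$context_predicates)) return(TRUE)
  env <- new.env(parent = baseenv())
  for (nm in names(ctx$variables)) {
    v <- ctx$variables[[nm]]
    assign(nm, if (inherits(v, "raster_layer")) v$values else v, envir = env)
  }
  out <- TRUE
  for (expr in cand$context_predicates) {
    val <- eval(parse(text = expr), envir = env)
    if (is.matrix(val)) {
      val[is.na(val)] <- FALSE
      out <- if (is.matrix(out)) out & val else
        if (isTRUE(out)) val else matrix(FALSE, nrow(val), ncol(val))
    } else {
      if (!isTRUE(val)) return(FALSE)
    }
  }
  out
}

#' Resolve a concept to a tree of computable components
#'
#' Chooses the top-ranked eligible candidate for the concept (candidates
#' whose guard predicates are false in this context are filtered out). When
#' predicates evaluate to spatial masks, several candidates may serve the
#' concept in disjoint segments of the grid (e.g. a RUSLE model on gentle
#' slopes and a probabilistic model on steep ones): ranked candidates are
#' assigned the still-uncovered cells of their mask until the grid is
#' covered. Model candidates recursively resolve their `requires` concepts;
#' datasets are leaves. Cyclic requirements are rejected. The returned tree
#' records every choice with its score breakdown (the provenance record);
#' resolution is a pure function of `(concept, registry, ctx)`.
#'
#' @param concept Concept tag to resolve.
#' @param registry List of [candidate_record()].
#' @param ctx A [resolution_context()].
#' @param target_path Optional tag path (defaults to `c(concept)`).
#' @return A `resolution_tree`: list with `concept`, `choices` (each with
#'   `candidate`, `score`, `breakdown`, `coverage`, and `children` —
#'   resolved trees for required concepts).
#' @export
resolve <- function(concept, registry, ctx, target_path = NULL,
                    .stack = character()) {
  if (concept %in% .stack)
    stop("cyclic requires: ", paste(c(.stack, concept), collapse = " -> "))
  if (length(registry) == 0) stop("empty registry")
  if (is.null(target_path)) target_path <- concept
  cands <- Filter(function(cc) cc$concept == concept, registry)
  if (length(cands) == 0)
    stop("unresolvable concept '", concept, "' (chain: ",
         paste(c(.stack, concept), collapse = " -> "), ")")
  cands <- Filter(function(cc) overlap_fraction(cc$extent, ctx$extent) > 0,
                  cands)
  if (length(cands) == 0)
    stop("no candidate for concept '", concept, "' overlaps the context")
  ranked <- rank_candidates(cands, ctx, target_path)
  choices <- list()
  covered <- FALSE  # FALSE, TRUE, or logical matrix of covered cells
  for (cand in ranked) {
    if (isTRUE(covered)) break
    g <- eval_predicates(cand, ctx)
    if (isFALSE(g)) next
    if (is.matrix(g)) {
      remaining <- if (is.matrix(covered)) g & !covered else g
      if (!any(remaining)) next
      coverage <- remaining
      covered <- if (is.matrix(covered)) covered | remaining else remaining
      if (all(covered)) covered <- TRUE
    } else {
      coverage <- if (is.matrix(covered)) !covered else TRUE
      covered <- TRUE
    }
    children <- list()
    if (cand$kind == "model" && length(cand$requires) > 0) {
      for (req in cand$requires)
        children[[req]] <- resolve(req, registry, ctx,
                                   .stack = c(.stack, concept))
    }
    choices[[length(choices) + 1]] <-
      list(candidate = cand, score = cand$score, breakdown = cand$breakdown,
           coverage = coverage, children = children)
  }
  if (length(choices) == 0)
    stop("no eligible candidate for concept '", concept,
         "' in this context")
  structure(list(concept = concept, choices = choices,
                 fully_covered = isTRUE(covered)),
            class = "resolution_tree")
}

#' Flatten a resolution tree into a provenance record
#'
#' One entry per choice: candidate id, concept, score, per-criterion
#' breakdown and the id of the parent candidate. Serializable to JSON with
#' `jsonlite::toJSON`.
#'
#' @param tree A `resolution_tree` from [resolve()].
#' @return List of provenance entries.
#' @export
provenance <- function(tree) {
  out <- list()
  walk <- function(node, parent) {
    for (ch in node$choices) {
      out[[length(out) + 1]] <<- list(
        candidate = ch$candidate$id, concept = node$concept,
        score = ch$score, breakdown = as.list(ch$breakdown),
        parent = parent)
      for (sub in ch$children) walk(sub, ch$candidate$id)
    }
  }
  walk(tree, NA)
  out
}

#' A named scenario of overrides
#'
#' @param name Scenario name.
#' @param overrides Named list, concept -> replacement
#'   [candidate_record()] or a layer file path (wrapped as a dataset
#'   candidate).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, overrides = list()) {
  stopifnot(is.list(overrides))
  structure(list(name = name, overrides = overrides), class = "scenario")
}

#' Apply scenario overrides to a registry
#'
#' Returns a new registry in which each overridden concept resolves to the
#' scenario's candidate with maximal priority; everything else — and the
#' baseline registry object — is untouched. Overriding a concept absent
#' from the baseline is a configuration error.
#'
#' @param registry List of [candidate_record()].
#' @param scen A [scenario()].
#' @return The new registry (list of candidates).
#' @export
apply_scenario <- function(registry, scen) {
  stopifnot(inherits(scen, "scenario"))
  known <- unique(vapply(registry, function(cc) cc$concept, ""))
  out <- registry
  for (concept in names(scen$overrides)) {
    if (!concept %in% known)
      stop("scenario '", scen$name, "' overrides unknown concept '",
           concept, "'")
    ov <- scen$overrides[[concept]]
    if (is.character(ov))
      ov <- candidate_record(id = paste0(scen$name, ":", concept),
                             concept = concept, kind = "dataset",
                             payload = ov)
    stopifnot(inherits(ov, "candidate_record"), ov$concept == concept)
    ov$scenario_priority <- TRUE
    out[[length(out) + 1]] <- ov
  }
  out
}
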