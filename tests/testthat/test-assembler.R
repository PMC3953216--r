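ctx0 <- function(...) {
  resolution_context(extent = c(xmin = 0, xmax = 10, ymin = 0, ymax = 10),
                     cell_size = 1, ...)
}

test_that("criterion scores follow the declared normalizations", {
  ctx <- ctx0()
  cand <- candidate_record("c1", "water", "dataset",
                           extent = c(xmin = 0, xmax = 10, ymin = 0,
                                      ymax = 10),
                           resolution = 1)
  s <- score_candidate(cand, ctx)
  expect_equal(unname(s$breakdown["user"]), 50)     # default user rank
  expect_equal(unname(s$breakdown["scale"]), 100)
  expect_equal(unname(s$breakdown["detail"]), 100)
  expect_equal(unname(s$breakdown["distance"]), 100)
  expect_equal(unname(s$breakdown["currency"]), 100)
  # weighted mean with uniform weights, recomputed by hand
  expect_equal(s$score, mean(s$breakdown))
  # identical candidates get identical scores
  s2 <- score_candidate(cand, ctx)
  expect_identical(s$score, s2$score)
  # semantic specificity: depth of matching path over target depth
  deep <- candidate_record("c2", "top-soil-carbon",
                           semantic_tags = c("carbon", "soil-carbon",
                                             "top-soil-carbon"))
  sd2 <- score_candidate(deep, ctx,
                         target_path = c("carbon", "soil-carbon"))
  expect_equal(unname(sd2$breakdown["semantic"]), 100)
  shallow <- candidate_record("c3", "carbon", semantic_tags = "carbon")
  sd3 <- score_candidate(shallow, ctx,
                         target_path = c("carbon", "soil-carbon"))
  expect_equal(unname(sd3$breakdown["semantic"]), 50)
})

test_that("finer local data outrank coarser global data, all else equal", {
  ctx <- ctx0()
  local_c <- candidate_record("local", "landcover", "dataset",
                              extent = c(xmin = 0, xmax = 10, ymin = 0,
                                         ymax = 10), resolution = 1)
  global_c <- candidate_record("global", "landcover", "dataset",
                               resolution = 30)
  rk <- rank_candidates(list(global_c, local_c), ctx)
  expect_equal(rk[[1]]$id, "local")
  # single candidate is trivially first
  expect_equal(rank_candidates(list(global_c), ctx)[[1]]$id, "global")
})

test_that("ranking equals a brute-force sort on random candidate pools", {
  ctx <- ctx0()
  for (seed in 1:5) {
    set.seed(seed)
    pool <- lapply(seq_len(8), function(i) {
      ur <- sample(c(-1, 10, 50, 90), 1)
      candidate_record(sprintf("cand%02d", i), "x", "dataset",
                       extent = c(xmin = 0, xmax = runif(1, 5, 10),
                                  ymin = 0, ymax = runif(1, 5, 10)),
                       resolution = sample(c(1, 2, 5), 1),
                       user_rank = if (ur < 0) NULL else ur)
    })
    rk <- rank_candidates(pool, ctx)
    scores <- vapply(pool, function(cc) score_candidate(cc, ctx)$score, 1)
    res <- vapply(pool, function(cc) cc$resolution, 1)
    ids <- vapply(pool, function(cc) cc$id, "")
    want <- ids[order(-scores, res, ids)]
    expect_equal(vapply(rk, function(cc) cc$id, ""), want)
  }
})

test_that("resolution builds trees, filters predicates, partitions by slope", {
  slope <- raster_layer(matrix(c(5, 10, 25, 40), 2, 2), grid_spec(2, 2))
  ctx <- ctx0(grid = slope$spec, variables = list(slope = slope))
  reg <- list(
    candidate_record("rusle", "erosion", "model", requires = "rainfall",
                     context_predicates = "slope <= 20"),
    candidate_record("steep_bn", "erosion", "model", requires = "rainfall",
                     context_predicates = "slope > 20"),
    candidate_record("rain", "rainfall", "dataset"))
  tree <- resolve("erosion", reg, ctx)
  ids <- vapply(tree$choices, function(ch) ch$candidate$id, "")
  expect_setequal(ids, c("rusle", "steep_bn"))
  expect_true(tree$fully_covered)
  # the two segments are disjoint and exhaustive
  masks <- lapply(tree$choices, function(ch) ch$coverage)
  expect_true(all(xor(masks[[1]], masks[[2]])))
  # children resolved recursively; datasets are leaves
  expect_equal(tree$choices[[1]]$children$rainfall$choices[[1]]$candidate$id,
               "rain")
  # single-dataset registry gives a one-leaf tree
  t1 <- resolve("rainfall", reg, ctx)
  expect_length(t1$choices, 1)
  expect_length(t1$choices[[1]]$children, 0)
})

test_that("resolution failures name the dependency chain; cycles are rejected", {
  ctx <- ctx0()
  reg <- list(candidate_record("m", "top", "model", requires = "missing"))
  expect_error(resolve("top", reg, ctx), "top -> missing")
  cyc <- list(
    candidate_record("a", "A", "model", requires = "B"),
    candidate_record("b", "B", "model", requires = "A"))
  expect_error(resolve("A", cyc, ctx), "cyclic")
})

test_that("resolution is pure and stable under removal of the winner", {
  ctx <- ctx0()
  for (seed in 1:5) {
    set.seed(seed)
    reg <- lapply(seq_len(5), function(i)
      candidate_record(sprintf("d%02d", i), "water", "dataset",
                       resolution = sample(c(1, 3, 9), 1),
                       user_rank = sample(c(20, 50, 80), 1)))
    t1 <- resolve("water", reg, ctx)
    t2 <- resolve("water", reg, ctx)
    expect_identical(provenance(t1), provenance(t2))
    winner <- t1$choices[[1]]$candidate$id
    rk <- rank_candidates(reg, ctx)
    runner_up <- rk[[2]]$id
    reg2 <- Filter(function(cc) cc$id != winner, reg)
    t3 <- resolve("water", reg2, ctx)
    expect_equal(t3$choices[[1]]$candidate$id, runner_up)
  }
})

test_that("exhaustive search over a 3-level registry picks the same tree", {
  ctx <- ctx0()
  set.seed(8)
  reg <- list(
    candidate_record("top_a", "svc", "model", requires = "mid",
                     user_rank = 80),
    candidate_record("top_b", "svc", "model", requires = "mid",
                     user_rank = 40),
    candidate_record("mid_a", "mid", "model", requires = "leaf",
                     user_rank = 30),
    candidate_record("mid_b", "mid", "model", requires = "leaf",
                     user_rank = 90),
    candidate_record("leaf_a", "leaf", "dataset", user_rank = 20),
    candidate_record("leaf_b", "leaf", "dataset", user_rank = 60))
  tree <- resolve("svc", reg, ctx)
  # oracle: independently pick max-score candidate at each concept
  best <- function(concept) {
    cands <- Filter(function(cc) cc$concept == concept, reg)
    sc <- vapply(cands, function(cc) score_candidate(cc, ctx)$score, 1)
    cands[[which.max(sc)]]$id
  }
  expect_equal(tree$choices[[1]]$candidate$id, best("svc"))
  expect_equal(tree$choices[[1]]$children$mid$choices[[1]]$candidate$id,
               best("mid"))
  expect_equal(tree$choices[[1]]$children$mid$choices[[1]]$children$leaf$
                 choices[[1]]$candidate$id, best("leaf"))
})

test_that("scenario overrides win resolution; the baseline registry is untouched", {
  ctx <- ctx0()
  reg <- list(
    candidate_record("model1", "erosion", "model", requires = "landcover"),
    candidate_record("lc_2000", "landcover", "dataset", user_rank = 90))
  # empty scenario: identical resolution
  reg_same <- apply_scenario(reg, scenario("noop", list()))
  expect_identical(provenance(resolve("erosion", reg_same, ctx)),
                   provenance(resolve("erosion", reg, ctx)))
  # land-cover override re-resolves every dependent model
  ov <- candidate_record("lc_2060", "landcover", "dataset", user_rank = 10)
  reg2 <- apply_scenario(reg, scenario("growth", list(landcover = ov)))
  t2 <- resolve("erosion", reg2, ctx)
  expect_equal(t2$choices[[1]]$children$landcover$choices[[1]]$candidate$id,
               "lc_2060")
  # baseline unchanged
  expect_length(reg, 2)
  expect_equal(resolve("erosion", reg, ctx)$choices[[1]]$children$landcover$
                 choices[[1]]$candidate$id, "lc_2000")
  expect_error(apply_scenario(reg, scenario("bad", list(nope = ov))),
               "unknown concept")
})
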