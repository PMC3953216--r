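strip_problem <- function(src, snk, use, rivalness = "rival",
                          benefit_type = "provisioning") {
  g <- grid_spec(1, length(src))
  dem <- raster_layer(matrix(rev(seq_along(src)), 1, length(src)), g)
  span_problem(raster_layer(matrix(src, 1), g),
               raster_layer(matrix(snk, 1), g),
               raster_layer(matrix(use, 1), g),
               benefit_spec(benefit_type, rivalness),
               router_spec("d8_downslope", dem = dem))
}

test_that("d8 directions: planes, pits, and the exhaustive descent oracle", {
  g <- grid_spec(4, 4)
  plane <- raster_layer(matrix(rep(4:1, each = 4), 4, 4), g)
  d <- route_d8(plane)
  expect_true(all(d[, 1:3] == 0))   # all flow East
  expect_true(all(d[, 4] == -1))    # east edge is terminal
  bowl <- matrix(2, 3, 3); bowl[2, 2] <- 0
  db <- route_d8(raster_layer(bowl, grid_spec(3, 3)))
  expect_equal(db[2, 2], -1)
  expect_equal(db[2, 1], 0); expect_equal(db[2, 3], 4)
  for (seed in 1:8) {
    set.seed(seed)
    z <- matrix(runif(36, 0, 10), 6, 6)
    dr <- route_d8(raster_layer(z, grid_spec(6, 6)))
    for (r in 1:6) for (c in 1:6)
      expect_equal(dr[r, c], steepest_descent(z, r, c))
  }
})

test_that("d8 flow graphs are acyclic on random DEMs", {
  for (seed in 1:10) {
    set.seed(seed)
    z <- matrix(runif(49, 0, 10), 7, 7)
    d <- route_d8(raster_layer(z, grid_spec(7, 7)))
    # walk from every cell; a cycle would exceed n steps
    for (r in 1:7) for (c in 1:7) {
      rr <- r; cc <- c; steps <- 0
      while (d[rr, cc] >= 0) {
        k <- d[rr, cc]
        rr2 <- rr + DR8[k + 1]; cc2 <- cc + DC8[k + 1]
        rr <- rr2; cc <- cc2
        steps <- steps + 1
        expect_lte(steps, 49)
        if (steps > 49) break
      }
    }
  }
})

test_that("single-path strip: sinks absorb before users, blocked use is the residual", {
  o <- run_span(strip_problem(c(10, 0, 0), c(0, 4, 0), c(0, 0, 10)))
  expect_equal(o$possible_use$values[1, 3], 10)
  expect_equal(o$actual_use$values[1, 3], 6)
  expect_equal(o$blocked_use$values[1, 3], 4)
  expect_equal(o$actual_sink$values[1, 2], 4)
  expect_equal(o$actual_source$values[1, 1], 6)
  expect_equal(o$inaccessible_use$values[1, 3], 0)
})

test_that("zero sink capacity makes possible and actual passes identical", {
  for (seed in 1:5) {
    p <- rand_d8_problem(seed)
    p$sink <- raster_layer(matrix(0, 5, 5), p$spec)
    o <- run_span(p)
    expect_equal(o$possible_use$values, o$actual_use$values)
    expect_equal(o$possible_flow$values, o$actual_flow$values)
    expect_equal(o$possible_source$values, o$actual_source$values)
    expect_true(all(o$blocked_use$values == 0))
    expect_true(all(o$blocked_flow$values == 0))
  }
})

test_that("rival d8 runs match the per-trajectory path-walking oracle", {
  for (seed in 1:30) {
    p <- rand_d8_problem(seed)
    o <- run_span(p)
    z <- p$router$dem$values
    want_a <- span_oracle_pass(p$source$values, p$sink$values, p$use$values,
                               TRUE, z)
    want_p <- span_oracle_pass(p$source$values, matrix(0, 5, 5),
                               p$use$values, TRUE, z)
    expect_equal(o$actual_flow$values, want_a$flow, tolerance = 1e-9)
    expect_equal(o$actual_use$values, want_a$use, tolerance = 1e-9)
    expect_equal(o$actual_sink$values, want_a$sink, tolerance = 1e-9)
    expect_equal(o$possible_flow$values, want_p$flow, tolerance = 1e-9)
    expect_equal(o$possible_use$values, want_p$use, tolerance = 1e-9)
    expect_equal(unname(o$terminal_outflow["actual"]), want_a$terminal,
                 tolerance = 1e-9)
  }
})

test_that("rival conservation and caps hold on random problems", {
  for (seed in 1:20) {
    p <- rand_d8_problem(seed)
    o <- run_span(p)
    tot <- span_totals(o)
    src_tot <- tot["theoretical_source"]
    balance <- tot["actual_use"] + tot["actual_sink"] +
      unname(o$terminal_outflow["actual"])
    expect_equal(unname(balance), unname(src_tot),
                 tolerance = 1e-6 * max(1, src_tot))
    expect_lte(tot["actual_use"],
               min(src_tot, tot["theoretical_use"]) + 1e-9)
    # source attribution is conservative: what sources deliver is what
    # users receive
    expect_equal(unname(tot["actual_source"]), unname(tot["actual_use"]),
                 tolerance = 1e-9 * max(1, src_tot))
  }
})

test_that("all taxonomy maps are nonnegative and possible dominates actual", {
  for (seed in 1:20) {
    p <- rand_d8_problem(seed)
    o <- run_span(p)
    for (nm in setdiff(names(o), "terminal_outflow"))
      expect_true(all(o[[nm]]$values >= 0), info = nm)
    for (x in c("source", "use", "flow"))
      expect_true(all(o[[paste0("possible_", x)]]$values -
                        o[[paste0("actual_", x)]]$values >= -1e-9), info = x)
  }
})

test_that("Table-3 identities are verified by independent recomputation", {
  for (seed in 1:10) {
    p <- rand_d8_problem(seed)
    o <- run_span(p)
    v <- function(nm) o[[nm]]$values
    expect_equal(v("blocked_use"), pmax(v("possible_use") - v("actual_use"), 0),
                 tolerance = 1e-9)
    expect_equal(v("blocked_flow"),
                 pmax(v("possible_flow") - v("actual_flow"), 0),
                 tolerance = 1e-9)
    expect_equal(v("blocked_source"),
                 pmax(v("possible_source") - v("actual_source"), 0),
                 tolerance = 1e-9)
    expect_equal(v("inaccessible_source"),
                 pmax(v("theoretical_source") - v("possible_source"), 0),
                 tolerance = 1e-9)
    expect_equal(v("inaccessible_use"),
                 pmax(v("theoretical_use") - v("possible_use"), 0),
                 tolerance = 1e-9)
    expect_equal(v("inaccessible_sink"),
                 pmax(v("theoretical_sink") - v("actual_sink"), 0),
                 tolerance = 1e-9)
  }
})

test_that("raising sink capacity never increases delivery, never decreases prevention", {
  for (seed in 1:8) {
    p <- rand_d8_problem(seed)
    o1 <- run_span(p)
    p2 <- p
    p2$sink <- raster_layer(p$sink$values + 1, p$spec)
    o2 <- run_span(p2)
    expect_lte(layer_total(o2$actual_use), layer_total(o1$actual_use) + 1e-9)
    # preventive problems share mechanics: blocked use = damage prevented
    expect_gte(layer_total(o2$blocked_use), layer_total(o1$blocked_use) - 1e-9)
  }
})

test_that("run_span is deterministic", {
  p <- rand_d8_problem(99)
  o1 <- run_span(p); o2 <- run_span(p)
  for (nm in setdiff(names(o1), "terminal_outflow"))
    expect_identical(o1[[nm]]$values, o2[[nm]]$values)
})

test_that("flat-terrain viewshed sees everything in range; walls block", {
  g <- grid_spec(5, 5)
  flat <- raster_layer(matrix(0, 5, 5), g)
  vs <- viewshed(flat, c(3, 3), max_distance = 2)
  expect_equal(vs$values[3, 3], 1)
  expect_equal(vs$values[3, 5], 1)
  expect_equal(vs$values[1, 1], 0)  # beyond range (distance 2*sqrt(2))
  wall <- matrix(0, 5, 5); wall[, 3] <- 1000
  vw <- viewshed(raster_layer(wall, g), c(3, 1), Inf)
  expect_equal(vw$values[3, 5], 0)
  expect_equal(vw$values[3, 2], 1)
})

test_that("viewshed matches the dense ray-sampling oracle on random terrain", {
  mismatches <- 0; total <- 0
  for (seed in 1:10) {
    set.seed(seed + 500)
    z <- matrix(runif(64, 0, 10), 8, 8)
    for (i in 1:2) z <- smooth_for_test(z)
    vs <- viewshed(raster_layer(z, grid_spec(8, 8)), c(4, 4), Inf)
    for (r in 1:8) for (c in 1:8) {
      total <- total + 1
      if (vs$values[r, c] != as.numeric(vs_oracle(z, 4, 4, r, c)))
        mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches / total, 0, tolerance = 0.01)
})

test_that("cost distance: origins are zero, uniform lines count steps, oracle agrees", {
  line <- raster_layer(matrix(1, 1, 3))
  cd <- cost_distance(line, matrix(c(1, 1), 1, 2))
  expect_equal(as.numeric(cd$values), c(0, 1, 2))
  expect_error(cost_distance(line, matrix(numeric(0), 0, 2)), "origin")
  for (seed in 1:5) {
    set.seed(seed)
    cost <- matrix(runif(36, 0.5, 3), 6, 6)
    org <- matrix(c(sample(6, 1), sample(6, 1)), 1, 2)
    got <- cost_distance(raster_layer(cost, grid_spec(6, 6)), org)
    want <- cost_oracle(cost, org)
    expect_equal(got$values, want, tolerance = 1e-9)
  }
})

test_that("non-rival delivery multiplies across users without depleting the source", {
  # one scenic source of ranked value 40 visible to 3 users
  g <- grid_spec(3, 3)
  src <- matrix(0, 3, 3); src[2, 2] <- 40
  use <- matrix(0, 3, 3); use[1, 1] <- 100; use[1, 3] <- 100; use[3, 2] <- 100
  p <- span_problem(raster_layer(src, g), raster_layer(matrix(0, 3, 3), g),
                    raster_layer(use, g),
                    benefit_spec("provisioning", "non_rival",
                                 carrier = "scenic quality"),
                    router_spec("line_of_sight",
                                dem = raster_layer(matrix(0, 3, 3), g),
                                max_distance = 10))
  o <- run_span(p)
  expect_equal(layer_total(o$actual_use), 3 * 40)
  expect_equal(o$actual_source$values[2, 2], 40)  # credit stays within source
  expect_equal(layer_total(o$inaccessible_source), 0)
})

test_that("line-of-sight sinks attenuate contributions additively with floor zero", {
  g <- grid_spec(1, 3)
  flatdem <- raster_layer(matrix(0, 1, 3), g)
  p <- span_problem(raster_layer(matrix(c(50, 0, 0), 1), g),
                    raster_layer(matrix(c(0, 15, 0), 1), g),
                    raster_layer(matrix(c(0, 0, 100), 1), g),
                    benefit_spec("provisioning", "non_rival"),
                    router_spec("line_of_sight", dem = flatdem,
                                max_distance = 10))
  o <- run_span(p)
  expect_equal(o$possible_use$values[1, 3], 50)
  expect_equal(o$actual_use$values[1, 3], 35)
  expect_equal(o$blocked_use$values[1, 3], 15)
  expect_equal(o$actual_sink$values[1, 2], 15)
})

test_that("access-cost routing allocates by travel cost with sink attenuation", {
  g <- grid_spec(1, 5)
  cost <- raster_layer(matrix(1, 1, 5), g)
  # user in the middle; near source cheap, far source beyond budget
  src <- matrix(c(8, 0, 0, 0, 20), 1)
  use <- matrix(c(0, 0, 10, 0, 0), 1)
  p <- span_problem(raster_layer(src, g), raster_layer(matrix(0, 1, 5), g),
                    raster_layer(use, g),
                    benefit_spec("provisioning", "rival"),
                    router_spec("access_cost", cost = cost, max_cost = 2.5))
  o <- run_span(p)
  expect_equal(o$actual_use$values[1, 3], 10)
  expect_equal(o$actual_source$values[1, 1], 8)  # near source exhausted first
  expect_equal(o$actual_source$values[1, 5], 2)
  # a sink on the path reduces delivery but not the claim
  p2 <- p
  p2$sink <- raster_layer(matrix(c(0, 3, 0, 0, 0), 1), g)
  o2 <- run_span(p2)
  expect_equal(o2$possible_use$values[1, 3], 10)
  expect_equal(o2$actual_use$values[1, 3], 7)
  expect_equal(o2$actual_sink$values[1, 2], 3)
})

test_that("well-mixed routing pools sources, nets out sinks, allocates by demand", {
  g <- grid_spec(2, 2)
  p <- span_problem(raster_layer(matrix(c(10, 0, 0, 0), 2, 2), g),
                    raster_layer(matrix(c(0, 3, 0, 0), 2, 2), g),
                    raster_layer(matrix(c(0, 0, 4, 8), 2, 2), g),
                    benefit_spec("provisioning", "rival", carrier = "CO2"),
                    router_spec("global_mix"))
  o <- run_span(p)
  expect_equal(o$actual_use$values[1, 2], 7 * 4 / 12)
  expect_equal(o$actual_use$values[2, 2], 7 * 8 / 12)
  expect_equal(layer_total(o$actual_sink), 3)
  expect_equal(layer_total(o$possible_use), 10)
  # flow maps are uniform pool density
  expect_true(all(abs(o$actual_flow$values - 7 / 4) < 1e-12))
})

test_that("demand sweeps report the spec ratio and saturate when supply allows", {
  expect_equal(sweep_result(15943889, 15443129)$ratio, 97)
  expect_equal(sweep_result(5958885, 304155269)$ratio, 5104)
  expect_error(sweep_result(0, 10), "zero")
  # abundant supply: delivered demand scales with the multiplier
  p <- strip_problem(c(1000, 0, 0, 0, 0), rep(0, 5), c(0, 0, 0, 0, 10))
  sw <- sustainability_sweep(p, c(1, 2, 5, 10))
  expect_equal(sw$current_need, 10)
  expect_equal(sw$max_potential, 100)
  expect_equal(sw$ratio, 1000)
  # constrained supply: potential tops out at deliverable supply
  p2 <- strip_problem(c(30, 0, 0, 0, 0), rep(0, 5), c(0, 0, 0, 0, 10))
  sw2 <- sustainability_sweep(p2, c(1, 2, 5, 10))
  expect_equal(sw2$max_potential, 30)
  expect_equal(sw2$ratio, 300)
})
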