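test_that("zero demand yields a zero optimum with optimal status", {
  inst <- make_small_instance(31)
  dem <- inst$scen$demand * 0
  scen <- scenario_set(as.numeric(inst$scen$probabilities), dem)
  sol <- solve_model(build_model(inst$region, inst$cov, scen,
                                 small_config()))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
})

test_that("the solver matches the oracle on seeded random instances", {
  for (seed in c(41, 42, 43, 44)) {
    inst <- make_small_instance(seed, n_nodes = 7, n_sites = 5, n_depots = 2)
    for (variant in c("BM", "CM", "IM"))
      expect_true(solver_matches_oracle(
        inst, small_config(variant, volume = seed %% 2 == 0, alpha = 1)))
  }
})

test_that("solved placements satisfy the solution invariants", {
  inst <- make_small_instance(45, n_nodes = 8, n_sites = 5, n_depots = 2)
  sol <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                 small_config("CM")))
  expect_equal(sol$status, "optimal")
  # at most one type per sited node
  expect_equal(anyDuplicated(sol$x_TC$id), 0)
  expect_equal(anyDuplicated(sol$x_AD$id), 0)
  # objective recomputed from the stored indicators matches
  p <- as.numeric(inst$scen$probabilities)
  recomputed <- sum(vapply(seq_along(p), function(w)
    p[w] * sum(inst$scen$demand[, , w] * sol$y[, , w]), numeric(1)))
  expect_equal(sol$objective, recomputed, tolerance = 1e-9)
  # pair indicators are the product of their parents
  if (nrow(sol$z) > 0) {
    expect_true(all(sol$z$site_id %in% sol$x_TC$id))
    expect_true(all(sol$z$depot_id %in% sol$x_AD$id))
  }
})

test_that("second-stage evaluation reproduces the solver's coverage", {
  for (seed in c(51, 52)) {
    inst <- make_small_instance(seed, n_nodes = 7, n_sites = 5, n_depots = 2)
    sol <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                   small_config("CM", p_AD = 2)))
    ev <- evaluate_second_stage(sol$x_TC, sol$x_AD, inst$cov, inst$scen)
    expect_identical(unname(ev$y), unname(sol$y))
    expect_equal(ev$objective, sol$objective,
                 tolerance = 1e-6 * max(1, sol$objective))
  }
})

test_that("closed-form evaluation follows the coverage definitions", {
  inst <- make_small_instance(53, n_nodes = 6, n_sites = 4, n_depots = 1)
  # nothing sited: nothing covered
  ev0 <- evaluate_second_stage(NULL, NULL, inst$cov, inst$scen)
  expect_true(all(!ev0$y))
  expect_equal(ev0$objective, 0)

  # a type-2-only placement covers type-2 by ground; severe coverage can
  # come only from air pairs (none, since no depot is open)
  j <- which(lengths(inst$cov$N) > 0)[1]
  site_id <- inst$cov$site_ids[inst$cov$N[[j]][1]]
  ev2 <- evaluate_second_stage(
    data.frame(id = site_id, type = 2), NULL, inst$cov, inst$scen)
  expect_true(any(ev2$y[, 2, 1]))
  expect_true(all(!ev2$y[, 1, 1]))
  expect_true(all(!ev2$u))
})

test_that("scenario-wise volume diagnostics report violations", {
  inst <- make_small_instance(54, n_nodes = 8, n_sites = 3)
  cfg <- small_config(volume = TRUE)
  # site everything type 2 at the busiest site and tighten the cap
  j <- which.max(vapply(inst$cov$Q, function(q)
    sum(inst$scen$demand[q, 2, ]), numeric(1)))
  cfg$V_max <- c(Inf, 0.5)
  ev <- evaluate_second_stage(
    data.frame(id = inst$cov$site_ids[j], type = 2), NULL,
    inst$cov, inst$scen, cfg)
  expect_gt(nrow(ev$violations), 0)
  expect_true(all(ev$violations$bound == "V_max"))
})

test_that("the printed-form minimum volume surfaces as infeasibility", {
  inst <- make_small_instance(55)
  cfg <- small_config(volume = TRUE)
  cfg$volume_min_form <- "printed"
  sol <- solve_model(build_model(inst$region, inst$cov, inst$scen, cfg))
  expect_equal(sol$status, "infeasible")
  orc <- brute_force_optimum(inst$region, inst$cov, inst$scen, cfg)
  expect_equal(orc$status, "infeasible")
  # the conditional default on the same instance is feasible
  cfg$volume_min_form <- "conditional"
  sol2 <- solve_model(build_model(inst$region, inst$cov, inst$scen, cfg))
  expect_true(sol2$status %in% c("optimal"))
})

test_that("an over-capacity fixed network is reported, not repaired", {
  inst <- make_small_instance(56, n_nodes = 10, n_sites = 4)
  cfg <- small_config("BM", volume = TRUE)
  cfg$V_max <- c(0.25, 0.25)  # existing facilities cannot meet this
  sol <- solve_model(build_model(inst$region, inst$cov, inst$scen, cfg))
  expect_equal(sol$status, "infeasible")
  # the exemption flag restores feasibility for the fixed facilities
  cfg$enforce_volume_on_fixed <- FALSE
  sol2 <- solve_model(build_model(inst$region, inst$cov, inst$scen, cfg))
  expect_equal(sol2$status, "optimal")
})

test_that("solution JSON round-trips through the writer and reader", {
  inst <- make_small_instance(57)
  sol <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                 small_config("CM")))
  f <- withr::local_tempfile(fileext = ".json")
  write_solution(sol, f)
  back <- read_solution(f)
  expect_equal(back$status, sol$status)
  expect_equal(back$objective, sol$objective)
  expect_equal(back$x_TC$id, sol$x_TC$id)
  expect_equal(unname(back$y), unname(sol$y))
})
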