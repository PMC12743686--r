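# fixture: 3 equal-demand nodes in one county, 2 covered, under 2 scenarios
hand_fixture <- function() {
  region <- region_data(
    nodes = data.frame(id = c("n1", "n2", "n3"), county = "Alpha",
                       lon = c(0, 1, 500), lat = 0),
    sites = data.frame(id = "h1", county = "Alpha", lon = 0, lat = 0,
                       designation = "none"),
    depots = data.frame(id = character(0), county = character(0),
                        lon = numeric(0), lat = numeric(0),
                        existing = logical(0)),
    coord_system = "planar-km")
  travel <- compute_travel_times(region)
  cov <- build_coverage_sets(travel, 60)      # n1, n2 reachable; n3 not
  dem <- array(1, dim = c(3, 2, 2),
               dimnames = list(region$nodes$id, c("type1", "type2"), NULL))
  scen <- scenario_set(c(0.5, 0.5), dem)
  list(region = region, cov = cov, scen = scen)
}

test_that("county coverage matches a hand computation", {
  fx <- hand_fixture()
  cfg <- model_config(p_TC = 2, p_AD = 0, r = c(2, 2), V_min = c(0, 0),
                      V_max = c(Inf, Inf), V_AD_max = Inf, variant = "CM")
  sol <- solve_model(build_model(fx$region, fx$cov, fx$scen, cfg))
  # only h1 exists: one type can be sited, covering 2 of 3 nodes for that
  # type -> 2 of 6 demand units
  expect_equal(sol$objective, 2)
  rep <- county_coverage_report(sol, fx$region, fx$scen, metric = "demand")
  expect_equal(rep$county$coverage, 100 * 2 / 6, tolerance = 1e-9)

  # with a second co-located site, both types cover 2 of 3 equal-demand
  # nodes: 66.7% demand-weighted
  region2 <- fx$region
  region2$sites <- rbind(region2$sites,
                         data.frame(id = "h2", county = "Alpha", lon = 0,
                                    lat = 0, designation = "none"))
  cov2 <- build_coverage_sets(compute_travel_times(region2), 60)
  sol2 <- solve_model(build_model(region2, cov2, fx$scen, cfg))
  rep2 <- county_coverage_report(sol2, fx$region, fx$scen,
                                 metric = "demand")
  expect_equal(rep2$county$coverage, 200 / 3, tolerance = 1e-9)
  repn <- county_coverage_report(sol2, fx$region, fx$scen, metric = "nodes")
  expect_equal(repn$county$coverage, 200 / 3, tolerance = 1e-9)
  expect_equal(rep2$overall, 100 * sol2$objective /
                 total_expected_demand(fx$scen), tolerance = 1e-9)
})

test_that("full coverage reports 100 and empty placements report 0", {
  pl <- generate_planted_instance(seed = 4, n_nodes = 30)
  cov <- build_coverage_sets(compute_travel_times(pl$region), 60)
  sol <- solve_model(build_model(pl$region, cov, pl$plant$scenarios,
                                 pl$plant$config))
  for (metric in c("demand", "nodes")) {
    rep <- county_coverage_report(sol, pl$region, pl$plant$scenarios,
                                  metric = metric)
    expect_true(all(abs(rep$county$coverage - 100) < 1e-9))
    expect_equal(rep$overall, 100, tolerance = 1e-9)
  }
  cfg0 <- pl$plant$config; cfg0$p_TC <- 0
  sol0 <- solve_model(build_model(pl$region, cov, pl$plant$scenarios, cfg0))
  rep0 <- county_coverage_report(sol0, pl$region, pl$plant$scenarios)
  with_demand <- !rep0$county$zero_demand
  expect_true(all(rep0$county$coverage[with_demand] == 0))
})

test_that("report comparison is an antisymmetric difference with totals", {
  inst <- make_small_instance(61, n_nodes = 9, n_sites = 5)
  bm <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                small_config("BM")))
  cm <- solve_model(build_model(inst$region, inst$cov, inst$scen,
                                small_config("CM")))
  ra <- county_coverage_report(bm, inst$region, inst$scen)
  rb <- county_coverage_report(cm, inst$region, inst$scen)
  self <- compare_solutions(ra, ra)
  expect_true(all(self$delta == 0))
  ab <- compare_solutions(ra, rb)
  ba <- compare_solutions(rb, ra)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$county[nrow(ab)], "TOTAL")
  expect_equal(ab$delta[nrow(ab)], ra$overall - rb$overall)

  rn <- county_coverage_report(bm, inst$region, inst$scen, metric = "nodes")
  expect_error(compare_solutions(ra, rn), "different metrics")
})

test_that("zero-demand counties are flagged and reported as covered", {
  fx <- hand_fixture()
  dem <- fx$scen$demand
  dem[3, , ] <- 0
  region <- fx$region
  region$nodes$county[3] <- "Empty"
  scen <- scenario_set(c(0.5, 0.5), dem)
  cfg <- model_config(p_TC = 1, p_AD = 0, r = c(1, 1), V_min = c(0, 0),
                      V_max = c(Inf, Inf), V_AD_max = Inf, variant = "CM")
  sol <- solve_model(build_model(region, fx$cov, scen, cfg))
  rep <- county_coverage_report(sol, region, scen)
  empty_row <- rep$county[rep$county$county == "Empty", ]
  expect_true(empty_row$zero_demand)
  expect_equal(empty_row$coverage, 100)
})
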