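# Seeded fixture builders used across the suite. All instances are small
# enough for the brute-force oracle and are generated in code at test time.

# region + travel + coverage sets + integer-demand scenarios
make_small_instance <- function(seed, n_nodes = 6, n_sites = 4,
                                n_depots = 1, designations = TRUE) {
  cfgr <- region_gen_config(
    seed = seed, n_counties = 3, n_nodes = n_nodes, n_sites = n_sites,
    n_depot_candidates = n_depots,
    n_existing_type1 = if (designations) 1 else 0,
    n_existing_type2 = if (designations) 1 else 0,
    n_existing_depots = if (designations) min(1, n_depots) else 0,
    area_extent = 150)
  region <- generate_region(cfgr)
  travel <- compute_travel_times(region)
  cov <- build_coverage_sets(travel, 60)
  set.seed(seed + 1000L)
  dem <- array(sample(0:5, n_nodes * 2 * 3, replace = TRUE),
               dim = c(n_nodes, 2, 3),
               dimnames = list(region$nodes$id, c("type1", "type2"), NULL))
  pool <- list(c(0.5, 0.3, 0.2), c(0.25, 0.5, 0.25), c(0.2, 0.2, 0.6))
  scen <- scenario_set(pool[[seed %% 3 + 1]], dem)
  list(region = region, travel = travel, cov = cov, scen = scen)
}

# configuration matching the small instances; volume bounds optional
small_config <- function(variant = "CM", volume = FALSE,
                         p_TC = 3, p_AD = 1, alpha = 0, mu = c(0, 0)) {
  model_config(p_TC = p_TC, p_AD = p_AD, r = c(1, 2),
               V_min = if (volume) c(1, 2) else c(0, 0),
               V_max = if (volume) c(25, 30) else c(Inf, Inf),
               V_AD_max = if (volume) 20 else Inf,
               S = 60, variant = variant,
               alpha_TC = alpha, alpha_AD = alpha, mu = mu)
}

# a 1-node/2-site/1-depot region with hand-set coordinates (planar miles
# are convenient: 1 km = 0.621 mi, so distances are set in km here)
tiny_region <- function() {
  region_data(
    nodes = data.frame(id = "n1", county = "A", lon = 0, lat = 0),
    sites = data.frame(id = c("h1", "h2"), county = "A",
                       lon = c(0, 200), lat = 0,
                       designation = c("type1", "none")),
    depots = data.frame(id = "d1", county = "A", lon = 0, lat = 0,
                        existing = TRUE),
    coord_system = "planar-km")
}

solver_matches_oracle <- function(inst, cfg) {
  m <- build_model(inst$region, inst$cov, inst$scen, cfg)
  sol <- solve_model(m)
  orc <- brute_force_optimum(inst$region, inst$cov, inst$scen, cfg)
  if (sol$status == "infeasible" || orc$status == "infeasible")
    return(sol$status == orc$status)
  identical(sol$objective, orc$objective)
}
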