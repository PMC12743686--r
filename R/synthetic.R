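#' Configuration for the synthetic service-area generator
#'
#' Defaults emulate the structure of a mixed urban/rural trauma service
#' area: 22 counties, 176 demand nodes (zip-code centroids), 86 candidate
#' hospital sites of which 24 carry existing designations (2 high-level,
#' 22 lower-level), and 7 existing aeromedical depots. Depot candidates are
#' co-located with candidate sites. Most counties are rural (low node
#' density); a minority hold dense urban clusters, and existing
#' designations concentrate in the densest county, mimicking a
#' hub-dominated benchmark network.
#'
#' @param seed integer RNG seed; generation is deterministic given it.
#' @param n_counties number of counties tiling the square extent.
#' @param n_nodes number of demand nodes.
#' @param n_sites number of candidate TCC sites.
#' @param n_depot_candidates number of depot candidates (drawn from site
#'   locations).
#' @param n_existing_type1,n_existing_type2 existing designation counts.
#' @param n_existing_depots existing depot count.
#' @param area_extent side of the square service area, kilometres
#'   (planar coordinates).
#' @param urban_fraction fraction of nodes placed in urban clusters.
#' @return A list of class `tn_region_gen_config`.
#' @export
region_gen_config <- function(seed = 1, n_counties = 22, n_nodes = 176,
                              n_sites = 86, n_depot_candidates = 86,
                              n_existing_type1 = 2, n_existing_type2 = 22,
                              n_existing_depots = 7, area_extent = 300,
                              urban_fraction = 0.7) {
  counts <- c(n_counties, n_nodes, n_sites, n_depot_candidates,
              n_existing_type1, n_existing_type2, n_existing_depots)
  stop_if(any(counts < 0) || any(counts != round(counts)),
          "counts must be non-negative integers")
  stop_if(n_counties < 1, "at least one county is required")
  stop_if(n_existing_type1 + n_existing_type2 > n_sites,
          "more existing designations than candidate sites")
  stop_if(n_existing_depots > n_depot_candidates,
          "more existing depots than depot candidates")
  stop_if(urban_fraction < 0 || urban_fraction > 1,
          "urban_fraction must be in [0, 1]")
  stop_if(area_extent <= 0, "area_extent must be positive")
  structure(as.list(environment()), class = "tn_region_gen_config")
}

#' Generate a synthetic trauma service area
#'
#' Counties tile the square extent as a rectangular grid; a minority of
#' counties are urban and receive `urban_fraction` of the nodes in Gaussian
#' clusters around their centers (the densest county is the hub), the rest
#' are rural with sparse uniform nodes. Candidate sites and depot
#' candidates are placed with probability proportional to local node
#' density (depot candidates co-located with sites). Existing type-1
#' designations go to the sites nearest the hub center; type-2 designations
#' and existing depots are drawn density-weighted with a hub bonus.
#'
#' @param cfg a [region_gen_config()].
#' @return A `tn_region` with `planar-km` coordinates.
#' @export
generate_region <- function(cfg) {
  stop_if(!inherits(cfg, "tn_region_gen_config"),
          "cfg must come from region_gen_config()")
  with_seed(cfg$seed, {
    nc <- cfg$n_counties
    ncol_g <- ceiling(sqrt(nc)); nrow_g <- ceiling(nc / ncol_g)
    cw <- cfg$area_extent / ncol_g; ch <- cfg$area_extent / nrow_g
    county_ids <- sprintf("C%02d", seq_len(nc))
    cell_col <- (seq_len(nc) - 1L) %% ncol_g
    cell_row <- (seq_len(nc) - 1L) %/% ncol_g
    cx <- (cell_col + 0.5) * cw; cy <- (cell_row + 0.5) * ch

    n_urban_cty <- max(1L, round(nc * 0.23))
    urban_cty <- sample.int(nc, n_urban_cty)
    hub <- urban_cty[1L]

    clip <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    place_in_county <- function(cty, n, clustered) {
      if (n == 0) return(NULL)
      if (clustered) {
        x <- stats::rnorm(n, cx[cty], cw / 8)
        y <- stats::rnorm(n, cy[cty], ch / 8)
      } else {
        x <- stats::runif(n, cell_col[cty] * cw, (cell_col[cty] + 1) * cw)
        y <- stats::runif(n, cell_row[cty] * ch, (cell_row[cty] + 1) * ch)
      }
      eps <- 1e-6
      data.frame(
        county = county_ids[cty],
        lon = clip(x, cell_col[cty] * cw + eps, (cell_col[cty] + 1) * cw - eps),
        lat = clip(y, cell_row[cty] * ch + eps, (cell_row[cty] + 1) * ch - eps),
        stringsAsFactors = FALSE)
    }

    # nodes: one per county first (every county holds zip codes), then the
    # urban share of the remainder goes to urban clusters (hub weighted
    # double) and the rest spreads uniformly over rural counties
    cnt <- integer(nc)
    rest <- cfg$n_nodes
    if (cfg$n_nodes >= nc) {
      cnt[] <- 1L
      rest <- cfg$n_nodes - nc
    }
    rural_cty <- setdiff(seq_len(nc), urban_cty)
    n_urban <- round(rest * cfg$urban_fraction)
    n_rural <- rest - n_urban
    if (length(rural_cty) == 0) {
      n_urban <- rest; n_rural <- 0L
    }
    if (n_urban > 0) {
      wts <- rep(1, n_urban_cty); wts[1L] <- 2
      cnt[urban_cty] <- cnt[urban_cty] +
        as.vector(stats::rmultinom(1, n_urban, wts))
    }
    if (n_rural > 0)
      cnt[rural_cty] <- cnt[rural_cty] +
        as.vector(stats::rmultinom(1, n_rural, rep(1, length(rural_cty))))
    nodes <- do.call(rbind, lapply(seq_len(nc), function(s)
      place_in_county(s, cnt[s], clustered = s %in% urban_cty)))
    if (is.null(nodes))
      nodes <- data.frame(county = character(0), lon = numeric(0),
                          lat = numeric(0), stringsAsFactors = FALSE)
    nodes <- data.frame(id = sprintf("N%03d", seq_len(nrow(nodes))), nodes,
                        stringsAsFactors = FALSE)

    # sites: density-proportional — jitter a sampled node, stay in county
    sample_near_nodes <- function(n, prefix) {
      if (n == 0 || nrow(nodes) == 0) {
        cty <- sample.int(nc, n, replace = TRUE)
        d <- do.call(rbind, lapply(seq_len(n), function(s)
          place_in_county(cty[s], 1L, clustered = FALSE)))
        d <- d %||% data.frame(county = character(0), lon = numeric(0),
                               lat = numeric(0), stringsAsFactors = FALSE)
      } else {
        ref <- sample.int(nrow(nodes), n, replace = TRUE)
        cty <- match(nodes$county[ref], county_ids)
        d <- data.frame(
          county = nodes$county[ref],
          lon = clip(nodes$lon[ref] + stats::rnorm(n, 0, cw / 20),
                     cell_col[cty] * cw + 1e-6,
                     (cell_col[cty] + 1) * cw - 1e-6),
          lat = clip(nodes$lat[ref] + stats::rnorm(n, 0, ch / 20),
                     cell_row[cty] * ch + 1e-6,
                     (cell_row[cty] + 1) * ch - 1e-6),
          stringsAsFactors = FALSE)
      }
      if (nrow(d) > 0) d <- data.frame(id = sprintf("%s%03d", prefix,
                                                    seq_len(nrow(d))), d,
                                       stringsAsFactors = FALSE)
      else d <- data.frame(id = character(0), d, stringsAsFactors = FALSE)
      d
    }
    sites <- sample_near_nodes(cfg$n_sites, "H")
    sites$designation <- rep("none", nrow(sites))

    # existing type-1: nearest to the hub center; type-2: density-weighted
    # with hub bonus among the rest
    if (cfg$n_existing_type1 > 0) {
      d_hub <- sqrt((sites$lon - cx[hub])^2 + (sites$lat - cy[hub])^2)
      sites$designation[order(d_hub)[seq_len(cfg$n_existing_type1)]] <-
        "type1"
    }
    if (cfg$n_existing_type2 > 0) {
      free <- which(sites$designation == "none")
      wt <- 1 + 3 * (sites$county[free] == county_ids[hub])
      pick <- free[sample.int(length(free), cfg$n_existing_type2,
                              prob = wt)]
      sites$designation[pick] <- "type2"
    }

    # depot candidates: co-located with a sample of sites
    if (cfg$n_depot_candidates > 0 && cfg$n_sites > 0) {
      ref <- if (cfg$n_depot_candidates <= cfg$n_sites)
        sample.int(cfg$n_sites, cfg$n_depot_candidates)
      else sample.int(cfg$n_sites, cfg$n_depot_candidates, replace = TRUE)
      depots <- data.frame(
        id = sprintf("D%03d", seq_len(cfg$n_depot_candidates)),
        county = sites$county[ref], lon = sites$lon[ref],
        lat = sites$lat[ref], stringsAsFactors = FALSE)
    } else {
      depots <- sample_near_nodes(cfg$n_depot_candidates, "D")
    }
    depots$existing <- rep(FALSE, nrow(depots))
    if (cfg$n_existing_depots > 0 && nrow(depots) > 0) {
      wt <- 1 + 3 * (depots$county == county_ids[hub])
      depots$existing[sample.int(nrow(depots), cfg$n_existing_depots,
                                 prob = wt)] <- TRUE
    }

    region_data(nodes, sites, depots, coord_system = "planar-km")
  })
}

#' Generate a planted full-coverage instance
#'
#' Constructs an instance whose optimum is known by construction: nodes
#' fall in well-separated clusters, each cluster center holds two
#' co-located candidate sites, and planting one type-1 and one type-2 TCC
#' per cluster covers every node's demand of both types by ground within
#' the time standard. Budgets allow exactly that placement and volume
#' bounds are slack, so the optimal objective equals the total expected
#' demand. Extra candidate sites beyond the two per cluster are decoys
#' scattered inside the clusters.
#'
#' @param seed integer RNG seed.
#' @param n_nodes number of demand nodes (>= 1).
#' @param n_sites total candidate sites; defaults to two per cluster, and
#'   must be at least that.
#' @param n_scenarios number of demand scenarios (uniform probabilities).
#' @param base_rate mean daily demand per node (split 20\% severe).
#' @return list with `region` (a `tn_region`), and `plant`: the scenario
#'   set (`scenarios`), the model configuration under which the plant is
#'   optimal (`config`), the planted `placement` (data.frame `id`, `type`)
#'   and its `objective` (the total expected demand).
#' @export
generate_planted_instance <- function(seed, n_nodes, n_sites = NULL,
                                      n_scenarios = 4, base_rate = 0.75) {
  stop_if(n_nodes < 1, "n_nodes must be >= 1")
  n_clusters <- max(1L, ceiling(n_nodes / 22))
  if (is.null(n_sites)) n_sites <- 2L * n_clusters
  stop_if(n_sites < 2L * n_clusters,
          "n_sites must be at least two per cluster (", 2L * n_clusters, ")")

  spacing <- 300  # km between cluster centers; far beyond ground reach
  radius <- 10    # km cluster radius; well inside the 60-min standard
  gcol <- ceiling(sqrt(n_clusters))
  centers <- data.frame(
    x = ((seq_len(n_clusters) - 1L) %% gcol) * spacing + spacing / 2,
    y = ((seq_len(n_clusters) - 1L) %/% gcol) * spacing + spacing / 2)
  county_ids <- sprintf("C%02d", seq_len(n_clusters))

  region_and_scen <- with_seed(seed, {
    cl <- rep(seq_len(n_clusters), length.out = n_nodes)
    ang <- stats::runif(n_nodes, 0, 2 * pi)
    rad <- radius * sqrt(stats::runif(n_nodes))
    # the first node of each cluster sits exactly on the center (and the
    # planted sites), so tiny instances are co-located by construction
    first <- !duplicated(cl)
    rad[first] <- 0
    nodes <- data.frame(
      id = sprintf("N%03d", seq_len(n_nodes)),
      county = county_ids[cl],
      lon = centers$x[cl] + rad * cos(ang),
      lat = centers$y[cl] + rad * sin(ang),
      stringsAsFactors = FALSE)

    n_decoy <- n_sites - 2L * n_clusters
    dcl <- if (n_decoy > 0) rep(seq_len(n_clusters), length.out = n_decoy)
    dang <- stats::runif(max(n_decoy, 0), 0, 2 * pi)
    drad <- radius * sqrt(stats::runif(max(n_decoy, 0)))
    sites <- data.frame(
      id = sprintf("H%03d", seq_len(n_sites)),
      county = c(rep(county_ids, each = 2),
                 if (n_decoy > 0) county_ids[dcl]),
      lon = c(rep(centers$x, each = 2),
              if (n_decoy > 0) centers$x[dcl] + drad * cos(dang)),
      lat = c(rep(centers$y, each = 2),
              if (n_decoy > 0) centers$y[dcl] + drad * sin(dang)),
      designation = "none", stringsAsFactors = FALSE)
    depots <- data.frame(id = character(0), county = character(0),
                         lon = numeric(0), lat = numeric(0),
                         existing = logical(0), stringsAsFactors = FALSE)
    region <- region_data(nodes, sites, depots, coord_system = "planar-km")

    demand <- array(0, dim = c(n_nodes, 2, n_scenarios))
    demand[, 1, ] <- stats::rpois(n_nodes * n_scenarios, base_rate * 0.2)
    demand[, 2, ] <- stats::rpois(n_nodes * n_scenarios, base_rate * 0.8)
    dimnames(demand) <- list(nodes$id, c("type1", "type2"), NULL)
    probs <- if (n_scenarios == 4) c(0.25, 0.25, 0.25, 0.25)
    else round(rep(1 / n_scenarios, n_scenarios), 3)
    scen <- scenario_set(probs, demand)
    list(region = region, scen = scen)
  })

  placement <- data.frame(
    id = sprintf("H%03d", seq_len(2L * n_clusters)),
    type = rep(1:2, n_clusters), stringsAsFactors = FALSE)
  cfg <- model_config(p_TC = 2 * n_clusters, p_AD = 0,
                      r = c(n_clusters, n_clusters),
                      V_min = c(0, 0), V_max = c(Inf, Inf), V_AD_max = Inf,
                      S = 60, variant = "CM")
  list(region = region_and_scen$region,
       plant = list(scenarios = region_and_scen$scen, config = cfg,
                    placement = placement,
                    objective =
                      total_expected_demand(region_and_scen$scen),
                    n_clusters = n_clusters))
}
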