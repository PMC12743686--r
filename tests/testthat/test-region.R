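test_that("region construction enforces ids, counties and designations", {
  nodes <- data.frame(id = c("a", "b"), county = "X", lon = 0:1, lat = 0:1)
  sites <- data.frame(id = "h", county = "X", lon = 0, lat = 0,
                      designation = "type1")
  depots <- data.frame(id = "d", county = "X", lon = 0, lat = 0,
                       existing = TRUE)
  r <- region_data(nodes, sites, depots, coord_system = "planar-km")
  expect_s3_class(r, "tn_region")
  expect_equal(unname(existing_sites(r)), "type1")
  expect_equal(existing_depots(r), "d")

  expect_error(region_data(rbind(nodes, nodes[1, ]), sites, depots,
                           "planar-km"), "duplicate ids")
  bad <- sites; bad$designation <- "level-IV"
  expect_error(region_data(nodes, bad, depots, "planar-km"), "designation")
  bad2 <- nodes; bad2$county <- ""
  expect_error(region_data(bad2, sites, depots, "planar-km"), "county")
  bad3 <- nodes; bad3$lon[1] <- NaN
  expect_error(region_data(bad3, sites, depots, "planar-km"), "coordinates")
})

test_that("geometric travel times follow distance/speed with circuity", {
  # 120 statute miles apart on a plane at 120 mph of air speed -> 60 min
  region <- region_data(
    nodes = data.frame(id = "n", county = "A", lon = 0, lat = 0),
    sites = data.frame(id = "h", county = "A",
                       lon = 120 * 1.609344, lat = 0, designation = "none"),
    depots = data.frame(id = "d", county = "A", lon = 0, lat = 0,
                        existing = FALSE),
    coord_system = "planar-km")
  tr <- compute_travel_times(region, ground_speed = 60, circuity = 1.5,
                             air_speed = 120, load_time = 5)
  expect_equal(tr$air_ij[1, 1], 60)
  expect_equal(tr$ground[1, 1], 120 * 1.5 / 60 * 60)  # 180 min
  expect_equal(tr$air_ki[1, 1], 0)                    # co-located depot
  expect_equal(tr$load_time, 5)                       # default passthrough

  # coincident node and site
  region2 <- region_data(
    nodes = data.frame(id = "n", county = "A", lon = 10, lat = 10),
    sites = data.frame(id = "h", county = "A", lon = 10, lat = 10,
                       designation = "none"),
    depots = data.frame(id = character(0), county = character(0),
                        lon = numeric(0), lat = numeric(0),
                        existing = logical(0)),
    coord_system = "planar-km")
  tr2 <- compute_travel_times(region2)
  expect_equal(tr2$ground[1, 1], 0)
  expect_equal(tr2$air_ij[1, 1], 0)
  expect_equal(tr2$load_time, 5)

  expect_error(compute_travel_times(region, ground_speed = 0), "speeds")
  expect_error(compute_travel_times(region, circuity = 0.9), "circuity")
})

test_that("great-circle distances are used for lonlat coordinates", {
  # one degree of longitude at the equator is about 69.17 statute miles
  region <- region_data(
    nodes = data.frame(id = "n", county = "A", lon = 0, lat = 0),
    sites = data.frame(id = "h", county = "A", lon = 1, lat = 0,
                       designation = "none"),
    depots = data.frame(id = character(0), county = character(0),
                        lon = numeric(0), lat = numeric(0),
                        existing = logical(0)),
    coord_system = "lonlat-degrees")
  tr <- compute_travel_times(region, ground_speed = 60, circuity = 1,
                             air_speed = 60)
  expect_equal(tr$ground[1, 1], 69.17, tolerance = 0.01)
})

test_that("region CSV and GeoJSON round-trips preserve the data", {
  inst <- make_small_instance(5)
  dir <- withr::local_tempdir()
  write_region(inst$region, dir)
  back <- read_region(dir, coord_system = "planar-km")
  expect_equal(back$nodes, inst$region$nodes)
  expect_equal(back$sites, inst$region$sites)
  expect_equal(back$depots, inst$region$depots)

  gj <- jsonlite::fromJSON(region_geojson(inst$region),
                           simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features,
                nrow(inst$region$nodes) + nrow(inst$region$sites) +
                  nrow(inst$region$depots))
  roles <- vapply(gj$features, function(f) f$properties$role, "")
  expect_equal(sum(roles == "site"), nrow(inst$region$sites))
})

test_that("explicit travel matrices can be supplied in long CSV format", {
  inst <- make_small_instance(7)
  dir <- withr::local_tempdir()
  long <- function(m) data.frame(
    from_id = rep(rownames(m), ncol(m)),
    to_id = rep(colnames(m), each = nrow(m)),
    minutes = as.vector(m))
  utils::write.csv(long(inst$travel$ground),
                   file.path(dir, "times_ground.csv"), row.names = FALSE)
  utils::write.csv(long(inst$travel$air_ki),
                   file.path(dir, "times_air_ki.csv"), row.names = FALSE)
  utils::write.csv(long(inst$travel$air_ij),
                   file.path(dir, "times_air_ij.csv"), row.names = FALSE)
  back <- read_travel_times(dir, inst$region)
  expect_equal(back$ground, inst$travel$ground)
  expect_equal(back$air_ki, inst$travel$air_ki)

  # missing pairs are an error, not silently imputed
  trunc <- long(inst$travel$ground)[-1, ]
  utils::write.csv(trunc, file.path(dir, "times_ground.csv"),
                   row.names = FALSE)
  expect_error(read_travel_times(dir, inst$region), "incomplete")
})
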