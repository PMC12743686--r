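#' Service-area data model
#'
#' A trauma service area is described by injury demand nodes (population
#' centroids, e.g. zip codes), candidate trauma care center (TCC) sites, and
#' candidate aeromedical depot (AD) sites. Existing designations mark the
#' benchmark network: sites may carry a level-I/II designation (`"type1"`,
#' severe injuries), a level-III-and-below designation (`"type2"`), or none;
#' depot candidates may already host a helicopter base.
#'
#' @param nodes data.frame with columns `id`, `county`, `lon`, `lat`.
#' @param sites data.frame with columns `id`, `county`, `lon`, `lat`,
#'   `designation` (one of `"none"`, `"type1"`, `"type2"`).
#' @param depots data.frame with columns `id`, `county`, `lon`, `lat`,
#'   `existing` (logical).
#' @param coord_system `"lonlat-degrees"` (great-circle distances) or
#'   `"planar-km"` (`lon`/`lat` hold planar x/y kilometres).
#' @return An object of class `tn_region`.
#' @export
region_data <- function(nodes, sites, depots,
                        coord_system = c("lonlat-degrees", "planar-km")) {
  coord_system <- match.arg(coord_system)
  nodes <- as.data.frame(nodes)
  sites <- as.data.frame(sites)
  depots <- as.data.frame(depots)

  check_tbl <- function(d, what, extra = character()) {
    need <- c("id", "county", "lon", "lat", extra)
    miss <- setdiff(need, names(d))
    stop_if(length(miss) > 0,
            what, " table is missing column(s): ", paste(miss, collapse = ", "))
    stop_if(anyDuplicated(d$id) > 0, "duplicate ids in ", what, " table")
    stop_if(any(is.na(d$county) | !nzchar(as.character(d$county))),
            "every ", what, " record needs a county label")
    stop_if(any(!is.finite(d$lon)) || any(!is.finite(d$lat)),
            "non-finite coordinates in ", what, " table")
    d$id <- as.character(d$id)
    d$county <- as.character(d$county)
    d
  }
  nodes <- check_tbl(nodes, "nodes")
  sites <- check_tbl(sites, "sites", "designation")
  depots <- check_tbl(depots, "depots", "existing")

  stop_if(!all(sites$designation %in% c("none", "type1", "type2")),
          "site designation must be one of 'none', 'type1', 'type2'")
  depots$existing <- as.logical(depots$existing)
  stop_if(any(is.na(depots$existing)), "depot 'existing' flag must be logical")

  structure(
    list(nodes = nodes, sites = sites, depots = depots,
         coord_system = coord_system),
    class = "tn_region")
}

#' @export
print.tn_region <- function(x, ...) {
  n1 <- sum(x$sites$designation == "type1")
  n2 <- sum(x$sites$designation == "type2")
  cat("Trauma service area (", x$coord_system, ")\n", sep = "")
  cat("  demand nodes : ", nrow(x$nodes), " in ",
      length(unique(x$nodes$county)), " counties\n", sep = "")
  cat("  TCC sites    : ", nrow(x$sites), " (existing: ", n1,
      " type1, ", n2, " type2)\n", sep = "")
  cat("  AD candidates: ", nrow(x$depots), " (existing: ",
      sum(x$depots$existing), ")\n", sep = "")
  invisible(x)
}

#' Existing designations of a region
#'
#' @param region a `tn_region`.
#' @return `existing_sites()`: a named character vector of site ids with
#'   values `"type1"`/`"type2"`; `existing_depots()`: character vector of
#'   depot ids.
#' @export
existing_sites <- function(region) {
  keep <- region$sites$designation != "none"
  stats::setNames(region$sites$designation[keep], region$sites$id[keep])
}

#' @rdname existing_sites
#' @export
existing_depots <- function(region) {
  region$depots$id[region$depots$existing]
}

#' Read and write region tables
#'
#' `read_region()` reads `nodes.csv`, `sites.csv`, `depots.csv` from a
#' directory; `write_region()` writes them. Column layout matches
#' [region_data()].
#'
#' @param dir directory path.
#' @param coord_system coordinate-system tag of the stored coordinates.
#' @return `read_region()` returns a `tn_region`.
#' @export
read_region <- function(dir, coord_system = c("lonlat-degrees", "planar-km")) {
  coord_system <- match.arg(coord_system)
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  region_data(rd("nodes.csv"), rd("sites.csv"), rd("depots.csv"),
              coord_system = coord_system)
}

#' @rdname read_region
#' @param region a `tn_region`.
#' @export
write_region <- function(region, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(region$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(region$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(region$depots, file.path(dir, "depots.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Export a region as GeoJSON point features
#'
#' Nodes, sites and depots become `Point` features with `role`, `id`,
#' `county` and designation properties. Planar coordinates are exported
#' as-is (unprojected).
#'
#' @param region a `tn_region`.
#' @param path output file; if `NULL` the GeoJSON string is returned.
#' @export
region_geojson <- function(region, path = NULL) {
  feat <- function(d, role, extra_col = NULL) {
    lapply(seq_len(nrow(d)), function(r) {
      props <- list(role = role, id = d$id[r], county = d$county[r])
      if (!is.null(extra_col)) props[[extra_col]] <- d[[extra_col]][r]
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(d$lon[r], d$lat[r])),
           properties = props)
    })
  }
  fc <- list(type = "FeatureCollection",
             features = c(feat(region$nodes, "node"),
                          feat(region$sites, "site", "designation"),
                          feat(region$depots, "depot", "existing")))
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
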