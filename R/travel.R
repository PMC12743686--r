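#' Travel-time container
#'
#' Holds the three travel-time matrices the coverage model needs, all in
#' minutes: ground driving time from each demand node to each TCC site
#' (`ground`), flying time from each depot to each node (`air_ki`), and
#' flying time from each node to each site (`air_ij`), plus the helicopter
#' patient-loading time (default 5 minutes).
#'
#' @param ground numeric matrix, nodes x sites, minutes.
#' @param air_ki numeric matrix, depots x nodes, minutes.
#' @param air_ij numeric matrix, nodes x sites, minutes.
#' @param load_time scalar minutes added to every air trip.
#' @return An object of class `tn_travel`.
#' @export
travel_data <- function(ground, air_ki, air_ij, load_time = 5) {
  ground <- as.matrix(ground); air_ki <- as.matrix(air_ki)
  air_ij <- as.matrix(air_ij)
  stop_if(!is.numeric(load_time) || length(load_time) != 1 ||
            !is.finite(load_time) || load_time < 0,
          "load_time must be a single non-negative number")
  for (m in list(ground, air_ki, air_ij)) {
    stop_if(length(m) > 0 && (any(!is.finite(m)) || any(m < 0)),
            "travel times must be finite and non-negative")
  }
  stop_if(nrow(ground) != nrow(air_ij) || ncol(ground) != ncol(air_ij),
          "ground and air node-to-site matrices must have identical shape")
  stop_if(ncol(air_ki) != nrow(ground),
          "air depot-to-node matrix must have one column per demand node")
  structure(list(ground = ground, air_ki = air_ki, air_ij = air_ij,
                 load_time = load_time),
            class = "tn_travel")
}

#' @export
print.tn_travel <- function(x, ...) {
  cat("Travel times: ", nrow(x$ground), " nodes x ", ncol(x$ground),
      " sites, ", nrow(x$air_ki), " depots; load time ", x$load_time,
      " min\n", sep = "")
  invisible(x)
}

#' Compute travel times from region geometry
#'
#' A geometric surrogate for road-network travel times: ground time is
#' straight-line (great-circle for `lonlat-degrees`, Euclidean for
#' `planar-km`) distance inflated by a circuity factor and divided by the
#' ground speed; air time is straight-line distance at helicopter speed.
#' Defaults: 45 mph ground with circuity 1.4, 120 mph helicopter, 5 minute
#' loading. Explicit matrices supplied via [travel_data()] bypass this
#' computation entirely.
#'
#' @param region a `tn_region`.
#' @param ground_speed ground speed, mph.
#' @param circuity road circuity multiplier (>= 1) applied to ground
#'   distances only.
#' @param air_speed helicopter cruise speed, mph.
#' @param load_time patient loading time, minutes.
#' @return A `tn_travel`.
#' @export
compute_travel_times <- function(region, ground_speed = 45, circuity = 1.4,
                                 air_speed = 120, load_time = 5) {
  stop_if(!inherits(region, "tn_region"), "region must be a tn_region")
  stop_if(ground_speed <= 0 || air_speed <= 0, "speeds must be positive")
  stop_if(circuity < 1, "circuity must be >= 1")
  d_ij <- distance_matrix_miles(region$nodes, region$sites,
                                region$coord_system)
  d_ki <- distance_matrix_miles(region$depots, region$nodes,
                                region$coord_system)
  ground <- d_ij * circuity / ground_speed * 60
  air_ij <- d_ij / air_speed * 60
  air_ki <- d_ki / air_speed * 60
  dimnames(ground) <- dimnames(air_ij) <-
    list(region$nodes$id, region$sites$id)
  dimnames(air_ki) <- list(region$depots$id, region$nodes$id)
  travel_data(ground, air_ki, air_ij, load_time = load_time)
}

#' Read travel-time matrices from long-format CSV files
#'
#' Reads `times_ground.csv`, `times_air_ki.csv`, `times_air_ij.csv`
#' (columns `from_id`, `to_id`, `minutes`; ground and air_ij are node->site,
#' air_ki is depot->node) and assembles a complete [travel_data()] object.
#' Every (from, to) pair must be present.
#'
#' @param dir directory containing the CSV files.
#' @param region the `tn_region` the matrices refer to.
#' @param load_time loading time, minutes.
#' @export
read_travel_times <- function(dir, region, load_time = 5) {
  fill <- function(file, rows, cols) {
    d <- utils::read.csv(file.path(dir, file), stringsAsFactors = FALSE)
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    d$from_id <- as.character(d$from_id); d$to_id <- as.character(d$to_id)
    bad <- !(d$from_id %in% rows) | !(d$to_id %in% cols)
    stop_if(any(bad), file, ": unknown ids in rows ",
            paste(utils::head(which(bad)), collapse = ", "))
    m[cbind(d$from_id, d$to_id)] <- d$minutes
    stop_if(anyNA(m), file, ": incomplete matrix (missing pairs)")
    m
  }
  travel_data(
    ground = fill("times_ground.csv", region$nodes$id, region$sites$id),
    air_ki = fill("times_air_ki.csv", region$depots$id, region$nodes$id),
    air_ij = fill("times_air_ij.csv", region$nodes$id, region$sites$id),
    load_time = load_time)
}
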