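# internal helpers: unit conversions, distance matrices, exact probability
# scaling

KM_PER_MILE <- 1.609344
METERS_PER_MILE <- 1609.344

#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# pairwise distance in statute miles between two coordinate tables
# (columns lon, lat). For "lonlat-degrees" distances are great-circle
# (haversine); for "planar-km" the coordinates are kilometres on a plane.
#' @noRd
distance_matrix_miles <- function(from, to, coord_system) {
  from <- as.matrix(from[, c("lon", "lat"), drop = FALSE])
  to <- as.matrix(to[, c("lon", "lat"), drop = FALSE])
  if (nrow(from) == 0L || nrow(to) == 0L) {
    return(matrix(numeric(0), nrow = nrow(from), ncol = nrow(to)))
  }
  if (coord_system == "lonlat-degrees") {
    geosphere::distm(from, to, fun = geosphere::distHaversine) / METERS_PER_MILE
  } else if (coord_system == "planar-km") {
    dx <- outer(from[, 1L], to[, 1L], "-")
    dy <- outer(from[, 2L], to[, 2L], "-")
    sqrt(dx^2 + dy^2) / KM_PER_MILE
  } else {
    stop("unknown coordinate system: ", coord_system, call. = FALSE)
  }
}

# Scenario probabilities with at most three decimal places admit exact
# integer arithmetic: return p * 1000 as integers, or NULL if not exact.
#' @noRd
scaled_probabilities <- function(p, scale = 1000) {
  s <- p * scale
  if (all(abs(s - round(s)) < 1e-9)) round(s) else NULL
}

# Expected covered demand, computed canonically: when demand is integral and
# probabilities have <= 3 decimals, the numerator sum(p_int * covered_w) is an
# exact integer and a single division yields a reproducible double. Otherwise
# plain double arithmetic. `covered_by_scenario` is the vector of covered
# demand per scenario.
#' @noRd
combine_scenarios <- function(covered_by_scenario, probabilities) {
  p_int <- scaled_probabilities(probabilities)
  if (!is.null(p_int) &&
      all(abs(covered_by_scenario - round(covered_by_scenario)) < 1e-9)) {
    return(sum(p_int * round(covered_by_scenario)) / 1000)
  }
  sum(probabilities * covered_by_scenario)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
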