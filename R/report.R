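#' Per-county coverage report
#'
#' Summarizes a solved model as coverage percentages per county, the level
#' at which siting studies report access. Two metrics are offered, because
#' published county tables rarely state which one they use:
#' \describe{
#'   \item{`"demand"`}{demand-weighted: 100 x expected covered demand /
#'     expected total demand in the county. Consistent with the model
#'     objective; the overall value equals 100 x objective / total expected
#'     demand.}
#'   \item{`"nodes"`}{node-fraction: the probability-weighted average over
#'     scenarios of the share of the county's nodes whose every
#'     positive-demand type is covered.}
#' }
#' A county with zero expected demand is reported as 100 and flagged.
#'
#' @param sol a `tn_solution` with a feasible placement.
#' @param region the `tn_region`.
#' @param scen the `tn_scenarios` used in the model.
#' @param metric `"demand"` or `"nodes"`.
#' @return An object of class `tn_coverage_report`: `metric`, `county`
#'   (data.frame with `county`, `coverage`, `zero_demand`), `overall`, and
#'   `per_scenario` coverage percentages.
#' @export
county_coverage_report <- function(sol, region, scen,
                                   metric = c("demand", "nodes")) {
  metric <- match.arg(metric)
  stop_if(!inherits(sol, "tn_solution"), "sol must be a tn_solution")
  stop_if(is.null(sol$y), "solution carries no coverage indicators (status ",
          sol$status, ")")
  counties <- sort(unique(region$nodes$county))
  p <- as.numeric(scen$probabilities)
  nW <- length(p)
  y <- sol$y

  county_rows <- lapply(counties, function(cty) {
    sel <- which(region$nodes$county == cty)
    if (metric == "demand") {
      num <- 0; den <- 0
      for (w in seq_len(nW)) {
        aw <- scen$demand[sel, , w, drop = FALSE][, , 1, drop = TRUE]
        aw <- matrix(aw, nrow = length(sel))
        yw <- matrix(y[sel, , w], nrow = length(sel))
        num <- num + p[w] * sum(aw * yw)
        den <- den + p[w] * sum(aw)
      }
      zero <- den <= 0
      data.frame(county = cty,
                 coverage = if (zero) 100 else 100 * num / den,
                 zero_demand = zero, stringsAsFactors = FALSE)
    } else {
      fr <- vapply(seq_len(nW), function(w) {
        ok <- vapply(sel, function(i) {
          pos <- scen$demand[i, , w] > 0
          all(y[i, , w][pos])
        }, logical(1))
        mean(ok)
      }, numeric(1))
      data.frame(county = cty, coverage = 100 * sum(p * fr) / sum(p),
                 zero_demand = FALSE, stringsAsFactors = FALSE)
    }
  })
  county <- do.call(rbind, county_rows) %||%
    data.frame(county = character(0), coverage = numeric(0),
               zero_demand = logical(0))

  per_w <- vapply(seq_len(nW), function(w) {
    tot <- sum(scen$demand[, , w])
    if (metric == "demand") {
      if (tot <= 0) 100 else
        100 * sum(scen$demand[, , w] * y[, , w]) / tot
    } else {
      if (dim(y)[1] == 0) return(100)
      ok <- vapply(seq_len(dim(y)[1]), function(i) {
        pos <- scen$demand[i, , w] > 0
        all(y[i, , w][pos])
      }, logical(1))
      100 * mean(ok)
    }
  }, numeric(1))
  names(per_w) <- scen$scenario_ids

  overall <- if (metric == "demand") {
    tot <- total_expected_demand(scen)
    cov_tot <- combine_scenarios(
      vapply(seq_len(nW), function(w) sum(scen$demand[, , w] * y[, , w]),
             numeric(1)), p)
    if (tot <= 0) 100 else 100 * cov_tot / tot
  } else {
    sum(p * per_w) / sum(p)
  }

  structure(list(metric = metric, county = county, overall = overall,
                 per_scenario = per_w),
            class = "tn_coverage_report")
}

#' @export
print.tn_coverage_report <- function(x, ...) {
  cat("County coverage (", x$metric, "-weighted): overall ",
      round(x$overall, 1), "%\n", sep = "")
  if (nrow(x$county) > 0) {
    d <- x$county
    d$coverage <- round(d$coverage, 1)
    print(d, row.names = FALSE)
  } else cat("  (no counties with demand nodes)\n")
  invisible(x)
}

#' Compare two coverage reports county by county
#'
#' Percentage-point improvement of report `a` over report `b` per county,
#' with a totals row comparing the overall percentages. Both reports must
#' use the same metric and cover the same counties.
#'
#' @param a,b `tn_coverage_report` objects on the same region and metric.
#' @return data.frame with columns `county`, `coverage_a`, `coverage_b`,
#'   `delta` (a - b, percentage points); the last row is `TOTAL`.
#' @export
compare_solutions <- function(a, b) {
  stop_if(!inherits(a, "tn_coverage_report") ||
            !inherits(b, "tn_coverage_report"),
          "both arguments must be coverage reports")
  stop_if(a$metric != b$metric, "reports use different metrics")
  stop_if(!identical(a$county$county, b$county$county),
          "reports cover different county sets")
  out <- data.frame(county = c(a$county$county, "TOTAL"),
                    coverage_a = c(a$county$coverage, a$overall),
                    coverage_b = c(b$county$coverage, b$overall),
                    stringsAsFactors = FALSE)
  out$delta <- out$coverage_a - out$coverage_b
  out
}

#' Read and write solutions as JSON
#'
#' Schema: `status`, `objective`, `gap`, `variant`, `placements` (`x_TC`,
#' `x_AD`, `z` as (id, type) records), `per_scenario_covered` (expected
#' covered demand per scenario weight 1), and the per-node coverage
#' indicator matrix `y` (identical across scenarios, stored once).
#'
#' @param sol a `tn_solution`.
#' @param path JSON file path.
#' @export
write_solution <- function(sol, path) {
  y1 <- if (!is.null(sol$y)) sol$y[, , 1, drop = TRUE] else NULL
  obj <- list(status = sol$status, objective = sol$objective,
              gap = sol$gap, variant = sol$variant,
              placements = list(x_TC = sol$x_TC, x_AD = sol$x_AD, z = sol$z),
              node_ids = sol$node_ids,
              scenario_ids = sol$scenario_ids,
              y = if (!is.null(y1)) unname(as.matrix(y1) * 1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  nW <- length(o$scenario_ids)
  y <- NULL
  if (!is.null(o$y) && length(o$y) > 0) {
    m <- matrix(as.logical(o$y), ncol = 2)
    y <- array(rep(m, nW), dim = c(nrow(m), 2, nW),
               dimnames = list(o$node_ids, c("type1", "type2"),
                               o$scenario_ids))
  }
  as_df <- function(d, cols) {
    if (is.null(d) || length(d) == 0)
      return(stats::setNames(
        data.frame(matrix(ncol = length(cols), nrow = 0)), cols))
    as.data.frame(d)
  }
  structure(list(status = o$status, objective = o$objective, gap = o$gap,
                 x_TC = as_df(o$placements$x_TC, c("id", "type")),
                 x_AD = as_df(o$placements$x_AD, c("id", "type")),
                 z = as_df(o$placements$z, c("depot_id", "site_id", "type")),
                 y = y, v = NULL, u = NULL,
                 n_explored = NA_integer_,
                 node_ids = o$node_ids, scenario_ids = o$scenario_ids,
                 variant = o$variant),
            class = "tn_solution")
}
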