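#' Scenario demand set
#'
#' A scenario is one realization of daily trauma demand per node and
#' facility type (type 1 = severe, type 2 = non-severe); the model optimizes
#' the probability-weighted expectation over scenarios. Demand may be
#' fractional (forecast output).
#'
#' @param probabilities numeric vector of scenario probabilities, all >= 0.
#'   The sum must lie in `[0.95, 1.05]`: published scenario tables are often
#'   rounded so a small deficit is tolerated as-is; use
#'   `renormalize = TRUE` to rescale to exactly 1.
#' @param demand numeric array `nodes x 2 x scenarios` (dimnames: node ids,
#'   c("type1","type2"), scenario ids), all entries >= 0.
#' @param scenario_ids optional character vector of scenario names.
#' @param renormalize divide probabilities by their sum.
#' @return An object of class `tn_scenarios`.
#' @export
scenario_set <- function(probabilities, demand, scenario_ids = NULL,
                         renormalize = FALSE) {
  probabilities <- as.numeric(probabilities)
  stop_if(length(probabilities) < 1, "at least one scenario is required")
  stop_if(any(!is.finite(probabilities)) || any(probabilities < 0),
          "probabilities must be finite and non-negative")
  demand <- as.array(demand)
  stop_if(length(dim(demand)) != 3 || dim(demand)[2] != 2,
          "demand must be a nodes x 2 x scenarios array")
  stop_if(dim(demand)[3] != length(probabilities),
          "demand third dimension must match the number of scenarios")
  stop_if(anyNA(demand) || any(demand < 0),
          "demand must be defined and non-negative for every ",
          "(node, type, scenario)")
  if (renormalize) probabilities <- probabilities / sum(probabilities)
  s <- sum(probabilities)
  stop_if(s < 0.95 || s > 1.05,
          "scenario probabilities sum to ", format(s),
          "; expected a value in [0.95, 1.05] (use renormalize = TRUE)")
  if (is.null(scenario_ids))
    scenario_ids <- dimnames(demand)[[3]] %||%
      paste0("s", seq_along(probabilities))
  dimnames(demand) <- list(
    dimnames(demand)[[1]] %||% as.character(seq_len(dim(demand)[1])),
    c("type1", "type2"),
    scenario_ids)
  structure(list(scenario_ids = scenario_ids,
                 probabilities = stats::setNames(probabilities, scenario_ids),
                 demand = demand),
            class = "tn_scenarios")
}

#' @export
print.tn_scenarios <- function(x, ...) {
  cat("Scenario set: ", length(x$scenario_ids), " scenarios, ",
      dim(x$demand)[1], " nodes\n", sep = "")
  cat("  probabilities: ",
      paste(sprintf("%s=%.3f", x$scenario_ids, x$probabilities),
            collapse = ", "), "\n", sep = "")
  cat("  expected total daily demand: ",
      round(total_expected_demand(x), 2), "\n", sep = "")
  invisible(x)
}

#' Total expected demand of a scenario set
#'
#' The probability-weighted total daily demand over all nodes and both
#' facility types; the coverage objective can never exceed this value.
#'
#' @param scen a `tn_scenarios`.
#' @export
total_expected_demand <- function(scen) {
  per_w <- apply(scen$demand, 3, sum)
  combine_scenarios(per_w, scen$probabilities)
}

# four-scenario probability table: three historical-demand scenarios plus a
# pandemic-demand scenario whose weight defines the instance
.instance_probs <- list(
  IN1 = c(0.33, 0.33, 0.33, 0.00),
  IN2 = c(0.16, 0.16, 0.16, 0.50),
  IN3 = c(0.25, 0.25, 0.25, 0.25),
  IN4 = c(0.083, 0.083, 0.083, 0.75))

#' Scenario probabilities for the four standard problem instances
#'
#' Returns the published four-scenario probability vector for instance
#' `IN1` (no pandemic demand), `IN2` (50\% pandemic), `IN3` (25\%) or `IN4`
#' (75\%). Scenarios 1-3 are "normal demand" years, scenario 4 is the
#' pandemic-demand scenario. The printed vectors do not all sum to exactly 1
#' (rounding); they are returned as printed unless `renormalize = TRUE`.
#'
#' @param instance_id one of `"IN1"`, `"IN2"`, `"IN3"`, `"IN4"`.
#' @param renormalize divide by the sum so it is exactly 1.
#' @return numeric vector of length 4.
#' @export
make_instance_probabilities <- function(instance_id, renormalize = FALSE) {
  stop_if(length(instance_id) != 1 || !instance_id %in% names(.instance_probs),
          "unknown instance id: ", paste(instance_id, collapse = ", "),
          " (expected IN1..IN4)")
  p <- .instance_probs[[instance_id]]
  if (renormalize) p <- p / sum(p)
  p
}

#' Sample synthetic demand scenarios
#'
#' Draws daily incident counts per node, type and scenario from independent
#' Poisson distributions, standing in for forecast-driven scenario
#' generation. Each node's mean total daily demand is split between severe
#' (type 1) and non-severe (type 2) demand by `severe_fraction`. One
#' designated scenario represents pandemic conditions: its means are the
#' base means times `covid_multiplier`.
#'
#' @param region a `tn_region`.
#' @param base_rates mean total daily demand per node; scalar or vector of
#'   length `nrow(region$nodes)`.
#' @param n_scenarios number of scenarios.
#' @param covid_scenario index of the pandemic scenario (default: the last),
#'   or `NA` for none.
#' @param covid_multiplier factor applied to the pandemic scenario's means.
#' @param severe_fraction fraction of each node's mean demand that is
#'   severe (type 1).
#' @param probabilities scenario probabilities; default uniform.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A `tn_scenarios`.
#' @export
generate_demand_scenarios <- function(region, base_rates, n_scenarios = 4,
                                      covid_scenario = n_scenarios,
                                      covid_multiplier = 1.5,
                                      severe_fraction = 0.2,
                                      probabilities = NULL,
                                      seed = 1) {
  stop_if(n_scenarios < 1, "n_scenarios must be >= 1")
  stop_if(any(base_rates < 0), "base_rates must be non-negative")
  stop_if(covid_multiplier < 0, "covid_multiplier must be non-negative")
  stop_if(severe_fraction < 0 || severe_fraction > 1,
          "severe_fraction must be in [0, 1]")
  nI <- nrow(region$nodes)
  rates <- rep_len(base_rates, nI)
  if (is.null(probabilities)) probabilities <- rep(1 / n_scenarios, n_scenarios)
  stop_if(length(probabilities) != n_scenarios,
          "probabilities must have one entry per scenario")

  mean1 <- rates * severe_fraction
  mean2 <- rates * (1 - severe_fraction)
  demand <- with_seed(seed, {
    a <- array(0, dim = c(nI, 2, n_scenarios))
    for (w in seq_len(n_scenarios)) {
      mult <- if (!is.na(covid_scenario) && w == covid_scenario)
        covid_multiplier else 1
      a[, 1, w] <- stats::rpois(nI, mean1 * mult)
      a[, 2, w] <- stats::rpois(nI, mean2 * mult)
    }
    a
  })
  dimnames(demand) <- list(region$nodes$id, c("type1", "type2"), NULL)
  ids <- paste0("s", seq_len(n_scenarios))
  if (!is.na(covid_scenario)) ids[covid_scenario] <- "covid"
  scenario_set(probabilities, demand, scenario_ids = ids)
}

#' Read and write scenario sets
#'
#' Long-format interchange: `demand.csv` with columns
#' `scenario_id,node_id,type,demand` (type is 1 or 2) and
#' `probabilities.csv` with columns `scenario_id,probability`.
#'
#' @param dir directory path.
#' @param region the `tn_region` providing the node universe.
#' @param renormalize passed to [scenario_set()].
#' @export
read_scenarios <- function(dir, region, renormalize = FALSE) {
  pr <- utils::read.csv(file.path(dir, "probabilities.csv"),
                        stringsAsFactors = FALSE)
  dm <- utils::read.csv(file.path(dir, "demand.csv"),
                        stringsAsFactors = FALSE)
  ids <- as.character(pr$scenario_id)
  nI <- nrow(region$nodes)
  demand <- array(NA_real_, dim = c(nI, 2, length(ids)),
                  dimnames = list(region$nodes$id, c("type1", "type2"), ids))
  demand[cbind(match(as.character(dm$node_id), region$nodes$id),
               as.integer(dm$type),
               match(as.character(dm$scenario_id), ids))] <- dm$demand
  stop_if(anyNA(demand), "demand.csv does not cover every ",
          "(node, type, scenario) combination")
  scenario_set(pr$probability, demand, scenario_ids = ids,
               renormalize = renormalize)
}

#' @rdname read_scenarios
#' @param scen a `tn_scenarios`.
#' @export
write_scenarios <- function(scen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(
    data.frame(scenario_id = scen$scenario_ids,
               probability = as.numeric(scen$probabilities)),
    file.path(dir, "probabilities.csv"), row.names = FALSE)
  g <- expand.grid(node_id = dimnames(scen$demand)[[1]],
                   type = 1:2, scenario_id = scen$scenario_ids,
                   stringsAsFactors = FALSE)
  g$demand <- as.vector(scen$demand)
  utils::write.csv(g[, c("scenario_id", "node_id", "type", "demand")],
                   file.path(dir, "demand.csv"), row.names = FALSE)
  invisible(dir)
}
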