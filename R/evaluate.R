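#' Closed-form second-stage evaluation of a first-stage placement
#'
#' Because the second stage has no coupling across nodes or scenarios, the
#' optimal coverage indicators for any fixed placement are computed directly:
#' demand of type `l` at node `i` is covered by ground iff a sited TCC of
#' type `l` is within the time standard, and severe demand (type 1) is
#' covered by air iff some eligible (site, depot) pair has a type-1 TCC at
#' the site and an open depot. The expected objective and per-scenario
#' volume diagnostics are returned.
#'
#' @param x_TC placement of TCCs: data.frame with columns `id`, `type`, or a
#'   named vector of types (1/2) by site id. At most one type per site.
#' @param x_AD placement of depots: data.frame with columns `id` (and
#'   optionally `type`), or a character vector of depot ids. Depots sited
#'   with a type-2 label carry no air capability.
#' @param cov a `tn_coverage`.
#' @param scen a `tn_scenarios`.
#' @param cfg optional `tn_config`; when supplied, per-scenario violations
#'   of the volume window and the depot severe-case cap at the sited
#'   facilities are reported.
#' @return list with `y`, `v`, `u` (`nodes x 2 x scenarios` logical arrays),
#'   `objective` (expected covered demand per day), `per_scenario` covered
#'   demand, and `violations` (data.frame; empty unless `cfg` given and the
#'   placement breaks a volume bound).
#' @export
evaluate_second_stage <- function(x_TC, x_AD = NULL, cov, scen, cfg = NULL) {
  nI <- cov$n_nodes; nJ <- cov$n_sites; nK <- cov$n_depots
  tc <- placement_vector(x_TC, cov$site_ids, "site")
  ad <- placement_vector(x_AD, cov$depot_ids, "depot")

  ground <- matrix(FALSE, nI, 2)
  for (l in 1:2) for (i in seq_len(nI))
    ground[i, l] <- any(tc[cov$N[[i]]] == l)
  air <- rep(FALSE, nI)
  for (i in seq_len(nI)) {
    Mi <- cov$M[[i]]
    if (nrow(Mi) > 0)
      air[i] <- any(tc[Mi[, "j"]] == 1L & ad[Mi[, "k"]] == 1L)
  }
  y <- ground
  y[, 1L] <- y[, 1L] | air

  nW <- length(scen$probabilities)
  dims <- list(cov$node_ids, c("type1", "type2"), scen$scenario_ids)
  rep_arr <- function(m) array(rep(m, nW), dim = c(nI, 2, nW),
                               dimnames = dims)
  u <- matrix(FALSE, nI, 2); u[, 1L] <- air
  per_w <- vapply(seq_len(nW), function(w)
    sum(scen$demand[, , w][y]), numeric(1))
  objective <- combine_scenarios(per_w, scen$probabilities)

  violations <- data.frame(facility = character(0), type = integer(0),
                           scenario = character(0), bound = character(0),
                           volume = numeric(0), limit = numeric(0))
  if (!is.null(cfg)) {
    for (j in which(tc > 0)) {
      l <- tc[j]
      for (w in seq_len(nW)) {
        A <- sum(scen$demand[cov$Q[[j]], l, w])
        if (A < cfg$V_min[l] - 1e-9)
          violations[nrow(violations) + 1L, ] <-
            list(cov$site_ids[j], l, scen$scenario_ids[w], "V_min", A,
                 cfg$V_min[l])
        if (A > cfg$V_max[l] + 1e-9)
          violations[nrow(violations) + 1L, ] <-
            list(cov$site_ids[j], l, scen$scenario_ids[w], "V_max", A,
                 cfg$V_max[l])
      }
    }
    for (k in which(ad == 1L)) {
      for (w in seq_len(nW)) {
        B <- sum(scen$demand[cov$O[[k]], 1L, w])
        if (B > cfg$V_AD_max + 1e-9)
          violations[nrow(violations) + 1L, ] <-
            list(cov$depot_ids[k], 1L, scen$scenario_ids[w], "V_AD_max", B,
                 cfg$V_AD_max)
      }
    }
  }

  list(y = rep_arr(y), v = rep_arr(ground), u = rep_arr(u),
       objective = objective, per_scenario = per_w,
       violations = violations)
}

# normalize a placement argument to a type vector indexed like `ids`
#' @noRd
placement_vector <- function(x, ids, what) {
  out <- rep(0L, length(ids))
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0)
    return(out)
  if (is.data.frame(x)) {
    stop_if(anyDuplicated(x$id) > 0,
            "placement sites ", what, " more than one type at a node")
    pos <- match(as.character(x$id), ids)
    stop_if(anyNA(pos), "unknown ", what, " id in placement")
    out[pos] <- if ("type" %in% names(x)) as.integer(x$type) else 1L
  } else if (!is.null(names(x))) {
    pos <- match(names(x), ids)
    stop_if(anyNA(pos), "unknown ", what, " id in placement")
    out[pos] <- as.integer(x)
  } else {
    pos <- match(as.character(x), ids)
    stop_if(anyNA(pos), "unknown ", what, " id in placement")
    out[pos] <- 1L
  }
  stop_if(any(!out %in% 0:2), "placement types must be 1 or 2")
  out
}
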