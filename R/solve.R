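# Exact solution of the deterministic-equivalent MILP.
#
# The model's second stage is separable: for any fixed first stage the
# optimal coverage indicators are exactly the coverage test (a node-type is
# covered iff a sited TCC of that type is within the standard by ground, or
# — for severe demand — an open (site, depot) pair reaches it by air), and
# the volume rows involve single first-stage binaries only. The solver
# therefore performs exact branch-and-bound over the first-stage site/depot
# decisions with a closed-form second stage and an admissible coverage
# bound. All structure (eligible sites, air pairs, budgets, caps,
# per-facility admissibility, objective weights) is reconstructed from the
# model's tagged constraint rows and objective coefficients, never from the
# raw inputs, so the solver independently verifies what the builder emitted.

# reconstruct search structure from a tn_model
#' @noRd
parse_model_structure <- function(model) {
  vars <- model$vars
  nJ <- model$n_sites; nK <- model$n_depots; nI <- model$n_nodes
  nW <- model$n_scenarios

  id_xTC <- matrix(NA_integer_, nJ, 2)
  w_xTC <- which(vars$role == "xTC")
  id_xTC[cbind(vars$j[w_xTC], vars$l[w_xTC])] <- w_xTC
  id_xAD <- matrix(NA_integer_, max(nK, 1), 2)
  w_xAD <- which(vars$role == "xAD")
  if (length(w_xAD) > 0)
    id_xAD[cbind(vars$k[w_xAD], vars$l[w_xAD])] <- w_xAD
  w_y <- which(vars$role == "y")
  id_y <- array(NA_integer_, c(nI, 2, nW))
  id_y[cbind(vars$i[w_y], vars$l[w_y], vars$w[w_y])] <- w_y

  # objective weights per (node, type): scenario-summed y coefficients;
  # exact integer numerators (x1000) kept when available
  w_il <- matrix(0, nI, 2)
  for (l in 1:2) for (i in seq_len(nI))
    w_il[i, l] <- sum(model$obj[id_y[i, l, ]])
  sc <- model$obj[w_y] * 1000
  exact_scale <- all(abs(sc - round(sc)) < 1e-6)
  w_il_scaled <- if (exact_scale) {
    m <- matrix(0, nI, 2)
    for (l in 1:2) for (i in seq_len(nI))
      m[i, l] <- sum(round(1000 * model$obj[id_y[i, l, ]]))
    m
  }

  first_stage <- vars$role %in% c("xTC", "xAD", "z")
  tags <- vapply(model$cons, `[[`, "", "tag")

  # ground-eligibility per (node, type) from family (9), scenario 1 rows
  N_il <- rep(list(rep(list(integer(0)), nI)), 2)
  for (cn in model$cons[tags == "9"]) {
    vrow <- cn$vars[1L]
    if (vars$w[vrow] != 1L) next
    i <- vars$i[vrow]; l <- vars$l[vrow]
    jj <- vars$j[cn$vars[-1L]]
    N_il[[l]][[i]] <- as.integer(jj)
  }
  # air pairs per node from family (10), scenario 1 rows
  pair_i <- integer(0); pair_j <- integer(0); pair_k <- integer(0)
  for (cn in model$cons[tags == "10"]) {
    vrow <- cn$vars[1L]
    if (vars$w[vrow] != 1L) next
    i <- vars$i[vrow]
    zv <- cn$vars[-1L]
    if (length(zv) == 0) next
    pair_i <- c(pair_i, rep(i, length(zv)))
    pair_j <- c(pair_j, vars$j[zv])
    pair_k <- c(pair_k, vars$k[zv])
  }

  # budgets and caps (absent family (11) means uncapped, as under CM)
  rhs_of <- function(tag) {
    hit <- model$cons[tags == tag]
    if (length(hit) == 0) NULL else vapply(hit, `[[`, 0, "rhs")
  }
  budget_TC <- rhs_of("2")[1] %||% Inf
  budget_AD <- rhs_of("4")[1] %||% Inf
  cap_l <- c(Inf, Inf)
  for (cn in model$cons[tags == "11"]) cap_l[cn$l] <- cn$rhs

  # single-variable first-stage rows (volume families and any other bound
  # emitted on one binary) become per-variable value restrictions
  allowed <- matrix(TRUE, nrow(vars), 2,
                    dimnames = list(NULL, c("v0", "v1")))
  infeasible_row <- FALSE
  handled <- tags %in% c("2", "3", "4", "5", "6", "7", "8", "9", "10", "11")
  generic <- list()
  for (cn in model$cons[!handled]) {
    if (!all(first_stage[cn$vars])) next
    if (length(cn$vars) == 1L) {
      v <- cn$vars; cf <- cn$coefs
      ok0 <- if (cn$sense == "<=") 0 <= cn$rhs + 1e-9 else 0 >= cn$rhs - 1e-9
      ok1 <- if (cn$sense == "<=") cf <= cn$rhs + 1e-9 else cf >= cn$rhs - 1e-9
      allowed[v, 1L] <- allowed[v, 1L] && ok0
      allowed[v, 2L] <- allowed[v, 2L] && ok1
      if (!ok0 && !ok1) infeasible_row <- TRUE
    } else {
      generic[[length(generic) + 1L]] <- cn
    }
  }
  # fixings from the variable table
  fx <- which(!is.na(vars$fixed) & first_stage)
  for (v in fx) {
    if (vars$fixed[v] == 1) allowed[v, 1L] <- FALSE
    if (vars$fixed[v] == 0) allowed[v, 2L] <- FALSE
  }

  # collapse to per-site / per-depot option sets
  opt_of <- function(ids) {
    # ids: the 2 variable ids (type 1, type 2) of one entity
    can1 <- allowed[ids, 2L]
    must1 <- !allowed[ids, 1L]
    if (any(must1 & !can1)) return(NULL)      # forced on yet inadmissible
    if (sum(must1) > 1) return(NULL)          # both types forced on
    if (any(must1)) return(which(must1))
    c(0L, which(can1))
  }
  site_opts <- lapply(seq_len(nJ), function(j) opt_of(id_xTC[j, ]))
  depot_opts <- if (nK > 0)
    lapply(seq_len(nK), function(k) opt_of(id_xAD[k, ])) else list()
  if (infeasible_row || any(vapply(site_opts, is.null, TRUE)) ||
      (nK > 0 && any(vapply(depot_opts, is.null, TRUE))))
    return(list(infeasible = TRUE))

  list(infeasible = FALSE,
       nI = nI, nJ = nJ, nK = nK, nW = nW,
       id_xTC = id_xTC, id_xAD = id_xAD, id_y = id_y,
       w_il = w_il, w_il_scaled = w_il_scaled,
       N_il = N_il, pair_i = pair_i, pair_j = pair_j, pair_k = pair_k,
       budget_TC = budget_TC, budget_AD = budget_AD, cap_l = cap_l,
       site_opts = site_opts, depot_opts = depot_opts,
       generic = generic, first_stage = first_stage, vars = vars)
}

# covered (node x type) indicator matrix for a complete assignment
#' @noRd
coverage_indicators <- function(st, tc, ad) {
  g <- matrix(FALSE, st$nI, 2)
  for (l in 1:2) for (i in seq_len(st$nI))
    g[i, l] <- any(tc[st$N_il[[l]][[i]]] == l)
  if (length(st$pair_i) > 0) {
    act <- tc[st$pair_j] == 1L & ad[st$pair_k] == 1L
    air_nodes <- unique(st$pair_i[act])
  } else air_nodes <- integer(0)
  y <- g
  y[air_nodes, 1L] <- TRUE
  list(y = y, ground = g, air_nodes = air_nodes)
}

#' @noRd
objective_of_mask <- function(st, y) {
  if (!is.null(st$w_il_scaled)) sum(st$w_il_scaled[y]) / 1000
  else sum(st$w_il[y])
}

# generic evaluation of unclassified first-stage rows (z taken as the
# product of its parents, its only beneficial value)
#' @noRd
generic_rows_ok <- function(st, tc, ad) {
  if (length(st$generic) == 0) return(TRUE)
  val <- numeric(nrow(st$vars))
  for (j in seq_len(st$nJ)) if (tc[j] > 0) val[st$id_xTC[j, tc[j]]] <- 1
  if (st$nK > 0) for (k in seq_len(st$nK)) if (ad[k] > 0)
    val[st$id_xAD[k, ad[k]]] <- 1
  zv <- which(st$vars$role == "z")
  if (length(zv) > 0)
    val[zv] <- val[st$id_xTC[cbind(st$vars$j[zv], st$vars$l[zv])]] *
      val[st$id_xAD[cbind(st$vars$k[zv], st$vars$l[zv])]]
  for (cn in st$generic) {
    lhs <- sum(cn$coefs * val[cn$vars])
    ok <- if (cn$sense == "<=") lhs <= cn$rhs + 1e-9 else lhs >= cn$rhs - 1e-9
    if (!ok) return(FALSE)
  }
  TRUE
}

# feasibility of a complete assignment w.r.t. budgets and caps
#' @noRd
assignment_feasible <- function(st, tc, ad) {
  if (sum(tc > 0) > st$budget_TC + 1e-9) return(FALSE)
  if (st$nK > 0 && sum(ad > 0) > st$budget_AD + 1e-9) return(FALSE)
  if (sum(tc == 1L) > st$cap_l[1] + 1e-9) return(FALSE)
  if (sum(tc == 2L) > st$cap_l[2] + 1e-9) return(FALSE)
  generic_rows_ok(st, tc, ad)
}

# admissible upper bound for a partial assignment: weight of node-types
# covered already or still coverable by a possible placement; ignores
# per-type caps (valid relaxation) but respects exhausted budgets
#' @noRd
partial_bound <- function(st, tc, ad) {
  open_TC <- sum(tc > 0, na.rm = TRUE) < st$budget_TC
  open_AD <- st$nK > 0 && sum(ad > 0, na.rm = TRUE) < st$budget_AD
  possible <- function(vec, idx, l, open) {
    any(vec[idx] == l, na.rm = TRUE) ||
      (open && any(is.na(vec[idx])))
  }
  tot <- 0
  for (l in 1:2) for (i in seq_len(st$nI)) {
    if (st$w_il[i, l] <= 0) next
    cov <- possible(tc, st$N_il[[l]][[i]], l, open_TC)
    if (!cov && l == 1L && length(st$pair_i) > 0) {
      sel <- st$pair_i == i
      if (any(sel)) {
        pj <- st$pair_j[sel]; pk <- st$pair_k[sel]
        jok <- (tc[pj] == 1L & !is.na(tc[pj])) | (is.na(tc[pj]) & open_TC)
        kok <- (ad[pk] == 1L & !is.na(ad[pk])) | (is.na(ad[pk]) & open_AD)
        cov <- any(jok & kok)
      }
    }
    if (cov) tot <- tot + st$w_il[i, l]
  }
  tot
}

#' Solve a siting model exactly
#'
#' Exact branch-and-bound over the first-stage siting decisions with a
#' closed-form second stage (see the package vignette for why this is
#' equivalent to solving the full deterministic-equivalent MILP). The
#' reported objective is recomputed canonically from the model's objective
#' coefficients; when demand is integral and scenario probabilities have at
#' most three decimals the arithmetic is exact (integer-scaled).
#'
#' @param model a `tn_model`.
#' @param gap_tolerance relative optimality gap at which search stops
#'   (default 0: prove optimality).
#' @param time_limit wall-clock limit in seconds; on expiry the incumbent is
#'   returned with status `"time-limit"`.
#' @param seed unused by the deterministic search; accepted so callers can
#'   treat all backends uniformly.
#' @return An object of class `tn_solution`: `status` (`"optimal"`,
#'   `"feasible-gap"`, `"infeasible"` or `"time-limit"`), `objective`,
#'   `gap`, placements `x_TC` / `x_AD`, pair indicators `z` (post-processed
#'   as the product of the parent binaries), second-stage indicator arrays
#'   `y`, `v`, `u`, and the number of search nodes explored.
#' @export
solve_model <- function(model, gap_tolerance = 0, time_limit = Inf,
                        seed = NULL) {
  stop_if(!inherits(model, "tn_model"), "model must be a tn_model")
  st <- parse_model_structure(model)
  if (st$infeasible)
    return(tn_solution(model, status = "infeasible"))

  nJ <- st$nJ; nK <- st$nK
  forced_tc <- rep(NA_integer_, nJ)
  for (j in seq_len(nJ))
    if (!0L %in% st$site_opts[[j]]) forced_tc[j] <- st$site_opts[[j]][1L]
  forced_ad <- rep(NA_integer_, max(nK, 0))
  if (nK > 0) for (k in seq_len(nK))
    if (!0L %in% st$depot_opts[[k]]) forced_ad[k] <- st$depot_opts[[k]][1L]

  # forced placements alone may already break budgets/caps
  base_tc <- forced_tc; base_ad <- forced_ad
  chk_tc <- base_tc; chk_tc[is.na(chk_tc)] <- 0L
  chk_ad <- base_ad; if (nK > 0) chk_ad[is.na(chk_ad)] <- 0L
  if (sum(chk_tc > 0) > st$budget_TC + 1e-9 ||
      (nK > 0 && sum(chk_ad > 0) > st$budget_AD + 1e-9) ||
      sum(chk_tc == 1L) > st$cap_l[1] + 1e-9 ||
      sum(chk_tc == 2L) > st$cap_l[2] + 1e-9)
    return(tn_solution(model, status = "infeasible"))

  # ---- greedy incumbent (incremental marginal gains) ------------------
  # site_members[[l]][[j]]: nodes whose type-l demand site j can cover
  site_members <- lapply(1:2, function(l) {
    mem <- rep(list(integer(0)), nJ)
    for (i in seq_len(st$nI)) for (j in st$N_il[[l]][[i]])
      mem[[j]] <- c(mem[[j]], i)
    mem
  })
  greedy_tc <- chk_tc; greedy_ad <- chk_ad
  repeat {
    cov_now <- coverage_indicators(st, greedy_tc, greedy_ad)$y
    best_gain <- 0; best_move <- NULL
    n_tc <- sum(greedy_tc > 0); n_ad <- if (nK > 0) sum(greedy_ad > 0) else 0
    if (n_tc < st$budget_TC) {
      for (j in seq_len(nJ)) {
        if (greedy_tc[j] > 0 || !is.na(base_tc[j])) next
        for (l in setdiff(st$site_opts[[j]], 0L)) {
          if (sum(greedy_tc == l) >= st$cap_l[l]) next
          mem <- site_members[[l]][[j]]
          gain <- sum(st$w_il[mem[!cov_now[mem, l]], l])
          if (l == 1L && length(st$pair_i) > 0) {
            sel <- st$pair_j == j & greedy_ad[st$pair_k] == 1L
            air_i <- unique(st$pair_i[sel])
            gain <- gain + sum(st$w_il[
              air_i[!cov_now[air_i, 1L] & !air_i %in% mem], 1L])
          }
          if (gain > best_gain) {
            best_gain <- gain; best_move <- list(kind = "site", j = j, l = l)
          }
        }
      }
    }
    if (nK > 0 && n_ad < st$budget_AD && length(st$pair_i) > 0) {
      for (k in seq_len(nK)) {
        if (greedy_ad[k] > 0 || !is.na(base_ad[k])) next
        if (!1L %in% st$depot_opts[[k]]) next
        sel <- st$pair_k == k & greedy_tc[st$pair_j] == 1L
        air_i <- unique(st$pair_i[sel])
        gain <- sum(st$w_il[air_i[!cov_now[air_i, 1L]], 1L])
        if (gain > best_gain) {
          best_gain <- gain; best_move <- list(kind = "depot", k = k)
        }
      }
    }
    if (is.null(best_move)) break
    if (best_move$kind == "site") greedy_tc[best_move$j] <- best_move$l
    else greedy_ad[best_move$k] <- 1L
  }

  inc <- list(obj = -Inf, tc = NULL, ad = NULL)
  if (assignment_feasible(st, greedy_tc, greedy_ad)) {
    inc <- list(obj = objective_of_mask(
      st, coverage_indicators(st, greedy_tc, greedy_ad)$y),
      tc = greedy_tc, ad = greedy_ad)
  }

  # ---- branch and bound ----------------------------------------------
  # entity order: sites by descending reachable weight, then depots
  site_pot <- vapply(seq_len(nJ), function(j) {
    s <- 0
    for (l in 1:2) for (i in seq_len(st$nI))
      if (j %in% st$N_il[[l]][[i]]) s <- s + st$w_il[i, l]
    s
  }, numeric(1))
  order_sites <- order(-site_pot)
  t0 <- Sys.time()
  n_explored <- 0L
  timed_out <- FALSE
  root_bound <- partial_bound(st, base_tc, base_ad)
  prune_tol <- function(b, incumbent) {
    if (!is.finite(incumbent)) return(FALSE)
    b <= incumbent * (1 + gap_tolerance) + 1e-9 * max(1, abs(incumbent))
  }

  recurse <- function(tc, ad, depth) {
    if (timed_out) return()
    n_explored <<- n_explored + 1L
    if (n_explored %% 256L == 0L &&
        as.numeric(Sys.time() - t0, units = "secs") > time_limit) {
      timed_out <<- TRUE
      return()
    }
    if (depth > nJ + nK) {
      if (!assignment_feasible(st, tc, ad)) return()
      obj <- objective_of_mask(st, coverage_indicators(st, tc, ad)$y)
      if (obj > inc$obj) inc <<- list(obj = obj, tc = tc, ad = ad)
      return()
    }
    is_site <- depth <= nJ
    ent <- if (is_site) order_sites[depth] else depth - nJ
    vals <- if (is_site) {
      if (!is.na(base_tc[ent])) base_tc[ent] else st$site_opts[[ent]]
    } else {
      if (!is.na(base_ad[ent])) base_ad[ent] else st$depot_opts[[ent]]
    }
    # try siting choices before skipping: good incumbents come early
    vals <- vals[order(vals == 0L)]
    for (v in vals) {
      tc2 <- tc; ad2 <- ad
      if (is_site) tc2[ent] <- v else ad2[ent] <- v
      # cheap partial feasibility
      if (sum(tc2 > 0, na.rm = TRUE) > st$budget_TC + 1e-9) next
      if (nK > 0 && sum(ad2 > 0, na.rm = TRUE) > st$budget_AD + 1e-9) next
      if (sum(tc2 == 1L, na.rm = TRUE) > st$cap_l[1] + 1e-9) next
      if (sum(tc2 == 2L, na.rm = TRUE) > st$cap_l[2] + 1e-9) next
      if (prune_tol(partial_bound(st, tc2, ad2), inc$obj)) next
      recurse(tc2, ad2, depth + 1L)
    }
  }

  if (!(is.finite(inc$obj) && prune_tol(root_bound, inc$obj))) {
    start_tc <- base_tc; start_ad <- base_ad
    recurse(start_tc, start_ad, 1L)
  }

  if (!is.finite(inc$obj))
    return(tn_solution(model,
                       status = if (timed_out) "time-limit" else "infeasible",
                       n_explored = n_explored))
  status <- if (timed_out) "time-limit" else "optimal"
  tn_solution(model, status = status, tc = inc$tc, ad = inc$ad, st = st,
              gap = if (timed_out) NA_real_ else gap_tolerance,
              n_explored = n_explored)
}

# assemble a tn_solution from an assignment (or an infeasible verdict)
#' @noRd
tn_solution <- function(model, status, tc = NULL, ad = NULL, st = NULL,
                        gap = NA_real_, n_explored = NA_integer_) {
  if (is.null(tc)) {
    return(structure(list(status = status, objective = NA_real_, gap = gap,
                          x_TC = NULL, x_AD = NULL, z = NULL,
                          y = NULL, v = NULL, u = NULL,
                          n_explored = n_explored,
                          site_ids = model$site_ids,
                          depot_ids = model$depot_ids,
                          node_ids = model$node_ids,
                          scenario_ids = model$scenario_ids,
                          variant = model$variant),
                     class = "tn_solution"))
  }
  cov <- coverage_indicators(st, tc, ad)
  nI <- st$nI; nW <- st$nW
  dims <- list(model$node_ids, c("type1", "type2"), model$scenario_ids)
  rep_arr <- function(m) array(rep(m, nW), dim = c(nI, 2, nW),
                               dimnames = dims)
  v_arr <- rep_arr(cov$ground)
  u2 <- matrix(FALSE, nI, 2)
  u2[cov$air_nodes, 1L] <- TRUE
  u_arr <- rep_arr(u2)
  y_arr <- rep_arr(cov$y)
  sited <- which(tc > 0)
  x_TC <- data.frame(id = model$site_ids[sited], type = tc[sited],
                     stringsAsFactors = FALSE)
  dep <- if (st$nK > 0) which(ad > 0) else integer(0)
  x_AD <- data.frame(id = model$depot_ids[dep],
                     type = if (length(dep)) ad[dep] else integer(0),
                     stringsAsFactors = FALSE)
  z <- if (st$nK > 0 && length(dep) > 0 && length(sited) > 0) {
    g <- expand.grid(k = dep, j = sited)
    g <- g[ad[g$k] == tc[g$j], , drop = FALSE]   # same type at both ends
    data.frame(depot_id = model$depot_ids[g$k],
               site_id = model$site_ids[g$j],
               type = tc[g$j], stringsAsFactors = FALSE)
  } else data.frame(depot_id = character(0), site_id = character(0),
                    type = integer(0))
  structure(list(status = status,
                 objective = objective_of_mask(st, cov$y),
                 gap = gap, x_TC = x_TC, x_AD = x_AD, z = z,
                 y = y_arr, v = v_arr, u = u_arr,
                 n_explored = n_explored,
                 site_ids = model$site_ids, depot_ids = model$depot_ids,
                 node_ids = model$node_ids,
                 scenario_ids = model$scenario_ids,
                 variant = model$variant),
            class = "tn_solution")
}

#' @export
print.tn_solution <- function(x, ...) {
  cat("Siting solution (", x$variant, "): status ", x$status, "\n", sep = "")
  if (!is.na(x$objective))
    cat("  expected covered demand/day: ", format(x$objective), "\n",
        sep = "")
  if (!is.null(x$x_TC))
    cat("  TCCs sited: ", nrow(x$x_TC), " (",
        sum(x$x_TC$type == 1), " type1, ", sum(x$x_TC$type == 2),
        " type2); depots: ", nrow(x$x_AD), "\n", sep = "")
  invisible(x)
}
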