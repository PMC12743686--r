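#' Enumeration limits for the brute-force oracle
#'
#' Guards against combinatorial blow-up: the oracle refuses instances whose
#' full enumeration `3^sites * 3^depots` exceeds the ceiling, or whose
#' cardinalities/budgets exceed the stated maxima. The oracle is
#' deliberately naive — no pruning beyond feasibility filtering — so the
#' limits keep it honest about what it can enumerate.
#'
#' @param max_sites,max_depots largest candidate-set sizes accepted.
#' @param max_budget_TC,max_budget_AD largest effective budgets accepted.
#' @param max_enumeration ceiling on the number of enumerated placements.
#' @export
oracle_limits <- function(max_sites = 8, max_depots = 3,
                          max_budget_TC = 5, max_budget_AD = 3,
                          max_enumeration = 250000) {
  structure(list(max_sites = max_sites, max_depots = max_depots,
                 max_budget_TC = max_budget_TC,
                 max_budget_AD = max_budget_AD,
                 max_enumeration = max_enumeration),
            class = "tn_oracle_limits")
}

#' Brute-force optimum by exhaustive enumeration
#'
#' Enumerates every assignment of types \{none, 1, 2\} to candidate sites
#' and depot candidates, applies the variant logic (benchmark fixings,
#' construction cap removal, improvement budgets) directly from the region
#' and configuration — deliberately re-implemented, independent of the
#' model builder and solver code paths — discards assignments violating
#' budgets, caps or the per-scenario volume constraints, evaluates each
#' survivor's expected covered demand in closed form, and returns the
#' maximum with one argmax. With integral demand and scenario probabilities
#' of at most three decimals, the objective arithmetic is exact
#' (integer-scaled).
#'
#' @param region a `tn_region`.
#' @param cov a `tn_coverage`.
#' @param scen a `tn_scenarios`.
#' @param cfg a `tn_config` (its `variant` field selects the variant).
#' @param limits an [oracle_limits()].
#' @return A list of class `tn_oracle_solution`: `status`, `objective`,
#'   `x_TC`, `x_AD`, `n_enumerated`, `n_feasible`.
#' @export
brute_force_optimum <- function(region, cov, scen, cfg,
                                limits = oracle_limits()) {
  nI <- cov$n_nodes; nJ <- cov$n_sites; nK <- cov$n_depots
  nW <- length(scen$probabilities)
  a <- scen$demand
  p <- as.numeric(scen$probabilities)

  budget_TC <- cfg$p_TC + if (cfg$variant == "IM") cfg$alpha_TC else 0
  budget_AD <- cfg$p_AD + if (cfg$variant == "IM") cfg$alpha_AD else 0
  caps <- switch(cfg$variant,
                 BM = cfg$r, CM = c(Inf, Inf), IM = cfg$r + cfg$mu)

  stop_if(nJ > limits$max_sites, "instance exceeds oracle site limit")
  stop_if(nK > limits$max_depots, "instance exceeds oracle depot limit")
  stop_if(budget_TC > limits$max_budget_TC,
          "instance exceeds oracle TCC budget limit")
  stop_if(budget_AD > limits$max_budget_AD,
          "instance exceeds oracle depot budget limit")
  n_enum <- 3^nJ * 3^nK
  stop_if(n_enum > limits$max_enumeration,
          "enumeration ceiling exceeded (", n_enum, " > ",
          limits$max_enumeration, " placements)")

  # variant fixings, re-derived from the region
  fixed_tc <- rep(NA_integer_, nJ)
  fixed_ad <- rep(NA_integer_, max(nK, 0))
  if (cfg$variant %in% c("BM", "IM")) {
    ex <- existing_sites(region)
    exd <- existing_depots(region)
    stop_if(length(ex) == 0 && length(exd) == 0,
            cfg$variant, " requires existing designations in the region")
    fixed_tc[match(names(ex), region$sites$id)] <-
      ifelse(ex == "type1", 1L, 2L)
    if (nK > 0) fixed_ad[match(exd, region$depots$id)] <- 1L
  }

  # exact integer scaling when available
  p_int <- scaled_probabilities(p)
  int_demand <- all(abs(a - round(a)) < 1e-9)
  use_scaled <- !is.null(p_int) && int_demand
  w_il <- matrix(0, nI, 2)
  for (l in 1:2) for (i in seq_len(nI)) {
    w_il[i, l] <- if (use_scaled) sum(p_int * round(a[i, l, ]))
    else sum(p * a[i, l, ])
  }
  scale_div <- if (use_scaled) 1000 else 1

  # per-facility volume admissibility (conditional form); the printed
  # unconditional minimum instead forces every positive-floor candidate on
  A_jl <- array(0, dim = c(max(nJ, 1), 2, nW))
  for (w in seq_len(nW)) for (l in 1:2) for (j in seq_len(nJ))
    A_jl[j, l, w] <- sum(a[cov$Q[[j]], l, w])
  adm_site <- matrix(TRUE, max(nJ, 1), 2)
  for (j in seq_len(nJ)) for (l in 1:2)
    adm_site[j, l] <- all(A_jl[j, l, ] >= cfg$V_min[l] - 1e-9) &&
      all(A_jl[j, l, ] <= cfg$V_max[l] + 1e-9)
  if (!cfg$enforce_volume_on_fixed)
    for (j in which(!is.na(fixed_tc))) adm_site[j, ] <- TRUE
  adm_dep <- rep(TRUE, max(nK, 1))
  if (nK > 0) for (k in seq_len(nK)) {
    B <- vapply(seq_len(nW), function(w) sum(a[cov$O[[k]], 1L, w]),
                numeric(1))
    adm_dep[k] <- all(B <= cfg$V_AD_max + 1e-9)
    if (!cfg$enforce_volume_on_fixed && !is.na(fixed_ad[k]))
      adm_dep[k] <- TRUE
  }

  # all site-type assignments, filtered to feasibility
  E <- as.matrix(expand.grid(rep(list(0:2), nJ)))
  if (nJ == 0) E <- matrix(integer(0), nrow = 1, ncol = 0)
  ok <- rowSums(E > 0) <= budget_TC &
    rowSums(E == 1) <= caps[1] & rowSums(E == 2) <= caps[2]
  for (j in which(!is.na(fixed_tc))) ok <- ok & E[, j] == fixed_tc[j]
  for (j in seq_len(nJ)) for (l in 1:2) {
    if (!adm_site[j, l]) ok <- ok & E[, j] != l
    if (cfg$volume_min_form == "printed" && cfg$V_min[l] > 1e-12)
      ok <- ok & E[, j] == l & adm_site[j, l]
  }
  E <- E[ok, , drop = FALSE]

  D <- if (nK > 0) as.matrix(expand.grid(rep(list(0:2), nK)))
  else matrix(integer(0), nrow = 1, ncol = 0)
  okd <- rowSums(D > 0) <= budget_AD
  if (nK > 0) {
    for (k in which(!is.na(fixed_ad))) okd <- okd & D[, k] == fixed_ad[k]
    for (k in seq_len(nK)) if (!adm_dep[k]) okd <- okd & D[, k] != 1L
  }
  D <- D[okd, , drop = FALSE]

  empty <- function(status) structure(
    list(status = status, objective = NA_real_, x_TC = NULL, x_AD = NULL,
         n_enumerated = n_enum, n_feasible = 0L),
    class = "tn_oracle_solution")
  if (nrow(E) == 0 || nrow(D) == 0) return(empty("infeasible"))

  # ground coverage per node-type for every surviving site assignment
  Ng <- matrix(FALSE, nI, max(nJ, 1))
  for (i in seq_len(nI)) Ng[i, cov$N[[i]]] <- TRUE
  C1 <- Ng %*% t(E == 1) > 0      # nI x nE
  C2 <- Ng %*% t(E == 2) > 0
  g2_obj <- as.vector(crossprod(w_il[, 2, drop = FALSE], C2))  # per E row

  pair_i <- integer(0); pair_j <- integer(0); pair_k <- integer(0)
  for (i in seq_len(nI)) {
    Mi <- cov$M[[i]]
    if (nrow(Mi) > 0) {
      pair_i <- c(pair_i, rep(i, nrow(Mi)))
      pair_j <- c(pair_j, Mi[, "j"]); pair_k <- c(pair_k, Mi[, "k"])
    }
  }

  nE <- nrow(E); nD <- nrow(D)
  obj <- matrix(0, nE, nD)
  if (length(pair_i) > 0 && nK > 0) {
    Zs <- (E == 1)[, pair_j, drop = FALSE]     # nE x npairs
    Dd <- (D == 1)[, pair_k, drop = FALSE]     # nD x npairs
    for (i in seq_len(nI)) {
      sel <- which(pair_i == i)
      air_i <- if (length(sel) > 0)
        (Zs[, sel, drop = FALSE] %*% t(Dd[, sel, drop = FALSE])) > 0
      else matrix(FALSE, nE, nD)
      y1 <- air_i | C1[i, ]                    # recycles C1 down columns
      obj <- obj + w_il[i, 1] * y1
    }
  } else {
    obj <- obj + as.vector(crossprod(w_il[, 1, drop = FALSE], C1))
  }
  obj <- obj + g2_obj

  best <- which(obj == max(obj), arr.ind = TRUE)[1, ]
  tc <- E[best[1], ]; ad <- D[best[2], ]
  structure(
    list(status = "optimal",
         objective = max(obj) / scale_div,
         x_TC = data.frame(id = region$sites$id[which(tc > 0)],
                           type = tc[tc > 0], stringsAsFactors = FALSE,
                           row.names = NULL),
         x_AD = data.frame(id = region$depots$id[which(ad > 0)],
                           type = ad[ad > 0], stringsAsFactors = FALSE,
                           row.names = NULL),
         n_enumerated = n_enum,
         n_feasible = nE * nD),
    class = "tn_oracle_solution")
}

#' @export
print.tn_oracle_solution <- function(x, ...) {
  cat("Brute-force oracle: status ", x$status, sep = "")
  if (!is.na(x$objective)) cat(", optimum ", format(x$objective), sep = "")
  cat(" (", x$n_feasible, " feasible of ", x$n_enumerated,
      " enumerated)\n", sep = "")
  invisible(x)
}
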