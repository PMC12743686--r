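#' Build the deterministic equivalent of the two-stage siting model
#'
#' Constructs the mixed-integer program whose solution maximizes expected
#' covered daily trauma demand. First-stage binaries decide where TCCs of
#' each type and aeromedical depots are sited and which (depot, site) pairs
#' are jointly open; second-stage binaries, replicated per scenario, record
#' whether demand at a node is covered by ground or by air. The two-stage
#' stochastic program collapses to a single MILP because the second stage is
#' a set of indicator constraints replicated per scenario.
#'
#' Constraint families (each row carries its family tag):
#' \describe{
#'   \item{2, 3}{TCC budget; at most one TCC type per site.}
#'   \item{4, 5}{depot budget; at most one depot per candidate.}
#'   \item{6, 7}{pair indicator linked below the TCC / depot binaries.}
#'   \item{8}{covered demand must be covered by ground or air.}
#'   \item{9}{ground coverage needs a sited TCC of that type within the
#'     time standard.}
#'   \item{10}{air coverage (severe demand only) needs an open (site, depot)
#'     pair within the time standard; the air indicator for non-severe
#'     demand is fixed to 0.}
#'   \item{11}{per-type cap on TCC counts.}
#'   \item{12, 13}{daily volume window at a sited TCC, per scenario. The
#'     minimum is applied conditionally (binding only where sited); the
#'     unconditional printed form is available as a diagnostic via
#'     `volume_min_form = "printed"` and is infeasible whenever a candidate
#'     with a positive floor is left unsited.}
#'   \item{14}{severe-case cap on demand air-reachable via a sited depot,
#'     per scenario.}
#' }
#'
#' @param region a `tn_region`.
#' @param cov a `tn_coverage` built from travel times for this region.
#' @param scen a `tn_scenarios`.
#' @param cfg a `tn_config`.
#' @return An object of class `tn_model`: variable table (`vars`), objective
#'   coefficients (`obj`), tagged constraint list (`cons`), and id metadata.
#' @export
build_deterministic_equivalent <- function(region, cov, scen, cfg) {
  stop_if(!inherits(region, "tn_region"), "region must be a tn_region")
  stop_if(!inherits(cov, "tn_coverage"), "cov must be a tn_coverage")
  stop_if(!inherits(scen, "tn_scenarios"), "scen must be a tn_scenarios")
  stop_if(!inherits(cfg, "tn_config"), "cfg must be a tn_config")
  nI <- cov$n_nodes; nJ <- cov$n_sites; nK <- cov$n_depots
  nW <- length(scen$probabilities)
  stop_if(nW == 0, "empty scenario set")
  stop_if(nI != dim(scen$demand)[1],
          "scenario demand and coverage sets disagree on the number of nodes")
  stop_if(nI != nrow(region$nodes) || nJ != nrow(region$sites) ||
            nK != nrow(region$depots),
          "coverage sets and region disagree on cardinalities")
  a <- scen$demand
  p <- as.numeric(scen$probabilities)

  # ---- variable table -------------------------------------------------
  rows <- list()
  add_vars <- function(role, grid) {
    grid$role <- rep(role, nrow(grid))
    rows[[length(rows) + 1L]] <<- grid
  }
  add_vars("xTC", expand.grid(j = seq_len(nJ), l = 1:2,
                              i = NA_integer_, k = NA_integer_,
                              w = NA_integer_))
  add_vars("xAD", expand.grid(k = seq_len(nK), l = 1:2,
                              i = NA_integer_, j = NA_integer_,
                              w = NA_integer_))
  add_vars("z", expand.grid(k = seq_len(nK), j = seq_len(nJ), l = 1:2,
                            i = NA_integer_, w = NA_integer_))
  for (role in c("y", "v", "u"))
    add_vars(role, expand.grid(i = seq_len(nI), l = 1:2, w = seq_len(nW),
                               j = NA_integer_, k = NA_integer_))
  cols <- c("role", "i", "j", "k", "l", "w")
  vars <- do.call(rbind, lapply(rows, function(d) d[, cols]))
  vars$fixed <- NA_real_
  nv <- nrow(vars)

  # index lookups
  off_xTC <- 0L
  idx_xTC <- function(j, l) off_xTC + (l - 1L) * nJ + j
  off_xAD <- 2L * nJ
  idx_xAD <- function(k, l) off_xAD + (l - 1L) * nK + k
  off_z <- off_xAD + 2L * nK
  idx_z <- function(k, j, l) off_z + ((l - 1L) * nJ + (j - 1L)) * nK + k
  off_y <- off_z + 2L * nK * nJ
  n_stage2 <- nI * 2L * nW
  idx_y <- function(i, l, w) off_y + ((w - 1L) * 2L + (l - 1L)) * nI + i
  idx_v <- function(i, l, w) off_y + n_stage2 + idx_y(i, l, w) - off_y
  idx_u <- function(i, l, w) off_y + 2L * n_stage2 + idx_y(i, l, w) - off_y
  vars$name <- c(
    sprintf("xTC[%s,%d]", rep(cov$site_ids, 2), rep(1:2, each = nJ)),
    sprintf("xAD[%s,%d]", rep(cov$depot_ids, 2), rep(1:2, each = nK)),
    sprintf("z[%s,%s,%d]",
            rep(cov$depot_ids, times = 2L * nJ),
            rep(rep(cov$site_ids, each = nK), 2),
            rep(1:2, each = nK * nJ)),
    sprintf("%s[%s,%d,%d]",
            rep(c("y", "v", "u"), each = n_stage2),
            rep(cov$node_ids, times = 2L * nW * 3L),
            rep(rep(1:2, each = nI), times = nW * 3L),
            rep(rep(seq_len(nW), each = 2L * nI), times = 3L)))

  # ---- objective: expected covered demand ------------------------------
  obj <- numeric(nv)
  for (w in seq_len(nW)) for (l in 1:2)
    obj[idx_y(seq_len(nI), l, w)] <- p[w] * a[, l, w]

  # ---- constraints -----------------------------------------------------
  cons <- vector("list", 0)
  add <- function(tag, v, cf, sense, rhs, l = NA_integer_) {
    cons[[length(cons) + 1L]] <<- list(tag = tag, vars = as.integer(v),
                                       coefs = as.numeric(cf), sense = sense,
                                       rhs = rhs, l = l)
  }

  # (2) TCC budget; (3) one type per site
  add("2", idx_xTC(rep(seq_len(nJ), 2), rep(1:2, each = nJ)),
      rep(1, 2 * nJ), "<=", cfg$p_TC)
  for (j in seq_len(nJ))
    add("3", idx_xTC(j, 1:2), c(1, 1), "<=", 1)
  # (4) depot budget; (5) one depot per candidate
  add("4", idx_xAD(rep(seq_len(nK), 2), rep(1:2, each = nK)),
      rep(1, 2 * nK), "<=", cfg$p_AD)
  for (k in seq_len(nK))
    add("5", idx_xAD(k, 1:2), c(1, 1), "<=", 1)
  # (6)/(7) pair indicator below both parents
  for (l in 1:2) for (j in seq_len(nJ)) for (k in seq_len(nK)) {
    add("6", c(idx_z(k, j, l), idx_xTC(j, l)), c(1, -1), "<=", 0)
    add("7", c(idx_z(k, j, l), idx_xAD(k, l)), c(1, -1), "<=", 0)
  }
  # (8)-(10) coverage logic, replicated per scenario
  for (w in seq_len(nW)) for (l in 1:2) for (i in seq_len(nI)) {
    add("8", c(idx_y(i, l, w), idx_v(i, l, w), idx_u(i, l, w)),
        c(1, -1, -1), "<=", 0)
    add("9", c(idx_v(i, l, w), idx_xTC(cov$N[[i]], l)),
        c(1, rep(-1, length(cov$N[[i]]))), "<=", 0)
    if (l == 1L) {
      Mi <- cov$M[[i]]
      add("10", c(idx_u(i, 1L, w),
                  if (nrow(Mi) > 0) idx_z(Mi[, "k"], Mi[, "j"], 1L)),
          c(1, rep(-1, nrow(Mi))), "<=", 0)
    } else {
      vars$fixed[idx_u(i, 2L, w)] <- 0
    }
  }
  # (11) per-type cap
  for (l in 1:2)
    add("11", idx_xTC(seq_len(nJ), l), rep(1, nJ), "<=", cfg$r[l], l = l)
  # (12)/(13) volume window at sited TCCs; (14) depot severe-case cap.
  # A[j,l,w] is the demand reachable from site j.
  for (w in seq_len(nW)) for (l in 1:2) {
    A <- vapply(seq_len(nJ),
                function(j) sum(a[cov$Q[[j]], l, w]), numeric(1))
    for (j in seq_len(nJ)) {
      if (cfg$volume_min_form == "conditional") {
        add("12", idx_xTC(j, l), A[j] - cfg$V_min[l], ">=", 0)
      } else {
        add("12", idx_xTC(j, l), A[j], ">=", cfg$V_min[l])
      }
      add("13", idx_xTC(j, l), A[j], "<=", cfg$V_max[l])
    }
  }
  for (w in seq_len(nW)) for (k in seq_len(nK)) {
    B <- sum(a[cov$O[[k]], 1L, w])
    add("14", idx_xAD(k, 1L), B, "<=", cfg$V_AD_max)
  }

  structure(list(vars = vars, obj = obj, cons = cons,
                 n_nodes = nI, n_sites = nJ, n_depots = nK,
                 n_scenarios = nW,
                 node_ids = cov$node_ids, site_ids = cov$site_ids,
                 depot_ids = cov$depot_ids,
                 scenario_ids = scen$scenario_ids,
                 variant = "none", cfg = cfg),
            class = "tn_model")
}

#' Apply a network-design variant to a built model
#'
#' \describe{
#'   \item{BM (benchmark)}{fixes the TCC binaries of all existing
#'     designations to 1 and fixes existing depots open; budgets are left at
#'     `p_TC`/`p_AD`, so the fixed network consumes the entire budget and the
#'     model purely assesses it.}
#'   \item{CM (construction)}{removes the per-type cap family (11) entirely
#'     and fixes nothing: the network is designed from an empty system.}
#'   \item{IM (improvement)}{BM fixings plus expansion headroom: the budget
#'     right-hand sides become `p_TC + alpha_TC`, `p_AD + alpha_AD` and
#'     `r_l + mu_l`.}
#' }
#'
#' @param model a `tn_model` from [build_deterministic_equivalent()].
#' @param region the `tn_region` carrying existing designations.
#' @param cfg a `tn_config`; `cfg$variant` selects the variant.
#' @return The modified `tn_model`.
#' @export
apply_variant <- function(model, region, cfg) {
  stop_if(!inherits(model, "tn_model"), "model must be a tn_model")
  variant <- cfg$variant
  if (variant %in% c("BM", "IM")) {
    ex <- existing_sites(region)
    exd <- existing_depots(region)
    stop_if(length(ex) == 0 && length(exd) == 0,
            variant, " requires existing designations in the region")
    for (s in seq_along(ex)) {
      j <- match(names(ex)[s], model$site_ids)
      stop_if(is.na(j), "existing site not among candidates: ", names(ex)[s])
      l <- if (ex[s] == "type1") 1L else 2L
      model$vars$fixed[which(model$vars$role == "xTC" &
                               model$vars$j == j & model$vars$l == l)] <- 1
    }
    for (id in exd) {
      k <- match(id, model$depot_ids)
      stop_if(is.na(k), "existing depot not among candidates: ", id)
      model$vars$fixed[which(model$vars$role == "xAD" &
                               model$vars$k == k & model$vars$l == 1L)] <- 1
    }
    if (!cfg$enforce_volume_on_fixed) {
      # exempt fixed facilities from the volume window by dropping their
      # single-variable volume rows
      fixed_ids <- which(model$vars$fixed %in% 1)
      keep <- vapply(model$cons, function(cn) {
        !(cn$tag %in% c("12", "13", "14") &&
            length(cn$vars) == 1L && cn$vars %in% fixed_ids)
      }, logical(1))
      model$cons <- model$cons[keep]
    }
  }
  if (variant == "CM") {
    model$cons <- Filter(function(cn) cn$tag != "11", model$cons)
  }
  if (variant == "IM") {
    for (idx in seq_along(model$cons)) {
      cn <- model$cons[[idx]]
      if (cn$tag == "2") model$cons[[idx]]$rhs <- cfg$p_TC + cfg$alpha_TC
      if (cn$tag == "4") model$cons[[idx]]$rhs <- cfg$p_AD + cfg$alpha_AD
      if (cn$tag == "11") model$cons[[idx]]$rhs <- cfg$r[cn$l] + cfg$mu[cn$l]
    }
  }
  model$variant <- variant
  model
}

#' Build and specialize the siting model in one call
#'
#' Convenience wrapper: [build_deterministic_equivalent()] followed by
#' [apply_variant()].
#'
#' @inheritParams build_deterministic_equivalent
#' @export
build_model <- function(region, cov, scen, cfg) {
  apply_variant(build_deterministic_equivalent(region, cov, scen, cfg),
                region, cfg)
}

#' @export
print.tn_model <- function(x, ...) {
  tags <- vapply(x$cons, `[[`, "", "tag")
  cat("Siting MILP (variant ", x$variant, "): ", nrow(x$vars),
      " binary variables, ", length(x$cons), " constraints\n", sep = "")
  tb <- table(tags)
  cat("  constraint families: ",
      paste(sprintf("(%s) x%d", names(tb), as.integer(tb)), collapse = ", "),
      "\n", sep = "")
  cat("  fixed variables: ", sum(x$vars$fixed %in% 1), " at 1, ",
      sum(x$vars$fixed %in% 0), " at 0\n", sep = "")
  invisible(x)
}

#' Export a model in LP text format
#'
#' Writes the objective, all constraint rows (named `<tag>_<n>`), fixings
#' and binary declarations in CPLEX LP format for solver-independent
#' inspection. Rows with an infinite right-hand side are omitted.
#'
#' @param model a `tn_model`.
#' @param path output file.
#' @export
write_lp <- function(model, path) {
  nm <- gsub("[^A-Za-z0-9_]", "_", model$vars$name)
  term <- function(cf, v) {
    paste(sprintf("%+.12g %s", cf, nm[v]), collapse = " ")
  }
  out <- c("Maximize",
           paste(" obj:", term(model$obj[model$obj != 0],
                               which(model$obj != 0))),
           "Subject To")
  cnt <- integer(0)
  for (cn in model$cons) {
    if (!is.finite(cn$rhs)) next
    cnt[cn$tag] <- (if (is.na(cnt[cn$tag])) 0L else cnt[cn$tag]) + 1L
    out <- c(out, sprintf(" c%s_%d: %s %s %.12g", cn$tag, cnt[cn$tag],
                          term(cn$coefs, cn$vars),
                          if (cn$sense == "<=") "<=" else ">=", cn$rhs))
  }
  fx <- which(!is.na(model$vars$fixed))
  if (length(fx) > 0) {
    out <- c(out, "Bounds",
             sprintf(" %s = %d", nm[fx], as.integer(model$vars$fixed[fx])))
  }
  out <- c(out, "Binary", paste("", nm), "End")
  writeLines(out, path)
  invisible(path)
}
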