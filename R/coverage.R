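#' Coverage sets under a time standard
#'
#' Derives the four eligibility sets used by the siting model from travel
#' times and the time standard `S` (the "golden hour", 60 minutes by
#' default):
#' \itemize{
#'   \item `N[[i]]`: sites within `S` of node `i` by ground
#'     (ground time <= S);
#'   \item `M[[i]]`: (site, depot) pairs within `S` of node `i` by air
#'     (depot-to-node + node-to-site flying time + loading time <= S);
#'   \item `Q[[j]]`: nodes within `S` of site `j` by ground (the dual of N);
#'   \item `O[[k]]`: nodes air-reachable via depot `k`, i.e. nodes for which
#'     some site closes the air triangle within `S` (existential reading).
#' }
#' All thresholds are inclusive. Sets hold integer indices into the node /
#' site / depot tables, carrying id names.
#'
#' @param travel a `tn_travel`.
#' @param S time standard, minutes.
#' @return An object of class `tn_coverage` with elements `S`, `load_time`,
#'   `N`, `M`, `Q`, `O` and cardinalities `n_nodes`, `n_sites`, `n_depots`.
#' @export
build_coverage_sets <- function(travel, S) {
  stop_if(!inherits(travel, "tn_travel"), "travel must be a tn_travel")
  stop_if(!is.numeric(S) || length(S) != 1 || !(S > 0),
          "S must be a single positive number")
  nI <- nrow(travel$ground); nJ <- ncol(travel$ground)
  nK <- nrow(travel$air_ki)
  node_ids <- rownames(travel$ground) %||% as.character(seq_len(nI))
  site_ids <- colnames(travel$ground) %||% as.character(seq_len(nJ))
  depot_ids <- rownames(travel$air_ki) %||% as.character(seq_len(nK))

  name_idx <- function(idx, ids) stats::setNames(idx, ids[idx])

  N <- lapply(seq_len(nI), function(i)
    name_idx(which(travel$ground[i, ] <= S), site_ids))
  Q <- lapply(seq_len(nJ), function(j)
    name_idx(which(travel$ground[, j] <= S), node_ids))

  # air pairs: t^A_ki + t^A_ij + t_load <= S
  M <- vector("list", nI)
  O_hit <- matrix(FALSE, nrow = nK, ncol = nI)
  for (i in seq_len(nI)) {
    if (nK == 0L || nJ == 0L) {
      M[[i]] <- matrix(integer(0), ncol = 2,
                       dimnames = list(NULL, c("j", "k")))
      next
    }
    tot <- outer(travel$air_ij[i, ], travel$air_ki[, i], "+") +
      travel$load_time                       # sites x depots
    hit <- which(tot <= S, arr.ind = TRUE)
    M[[i]] <- matrix(c(hit[, 1L], hit[, 2L]), ncol = 2,
                     dimnames = list(NULL, c("j", "k")))
    if (nrow(hit) > 0) O_hit[unique(hit[, 2L]), i] <- TRUE
  }
  O <- lapply(seq_len(nK), function(k)
    name_idx(which(O_hit[k, ]), node_ids))

  structure(list(S = S, load_time = travel$load_time,
                 N = N, M = M, Q = Q, O = O,
                 n_nodes = nI, n_sites = nJ, n_depots = nK,
                 node_ids = node_ids, site_ids = site_ids,
                 depot_ids = depot_ids),
            class = "tn_coverage")
}

#' @export
print.tn_coverage <- function(x, ...) {
  cat("Coverage sets at S = ", x$S, " min (load ", x$load_time, " min)\n",
      sep = "")
  cat("  ground-covered node fraction: ",
      round(mean(lengths(x$N) > 0), 3), "\n", sep = "")
  cat("  air pairs per node (mean): ",
      round(mean(vapply(x$M, nrow, 0L)), 1), "\n", sep = "")
  invisible(x)
}
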