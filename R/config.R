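#' Model configuration
#'
#' Parameters of the siting model and its network-design variants. Defaults
#' follow the standard study set-up for a ~22-county service area: budgets of
#' 24 TCCs and 7 aeromedical depots, per-type caps of 2 high-level and 22
#' lower-level centers, daily volume window \[1, 5\] per sited center, depot
#' severe-case cap 7 per day, 60-minute time standard.
#'
#' @param p_TC maximum number of TCCs sited.
#' @param p_AD maximum number of aeromedical depots sited.
#' @param r length-2 vector: maximum TCC count per type.
#' @param V_min length-2 vector: minimum daily volume required to site a TCC
#'   of each type (financial-viability floor; applied only to sited
#'   facilities).
#' @param V_max length-2 vector: maximum daily volume allowed at a sited TCC.
#' @param V_AD_max maximum daily severe-case volume handled via a depot.
#' @param S time standard, minutes.
#' @param variant `"BM"` (benchmark: existing facilities fixed), `"CM"`
#'   (construction: empty system, per-type cap dropped) or `"IM"`
#'   (improvement: existing fixed plus expansion headroom).
#' @param alpha_TC,alpha_AD additional TCCs/depots allowed under `"IM"`.
#' @param mu length-2 vector: additional per-type cap headroom under `"IM"`.
#' @param enforce_volume_on_fixed apply the volume window to facilities fixed
#'   by BM/IM as well (default). With `FALSE`, fixed facilities are exempt;
#'   infeasibility of a fixed network is reported, never silently repaired.
#' @param volume_min_form `"conditional"` (default): the minimum-volume
#'   constraint binds only where a facility is sited. `"printed"` is a
#'   diagnostic mode that requires every candidate's reachable demand to meet
#'   the floor unconditionally; with a positive floor it renders any model
#'   with an unsited candidate infeasible, which is why the conditional form
#'   is the default.
#' @return An object of class `tn_config`.
#' @export
model_config <- function(p_TC = 24, p_AD = 7, r = c(2, 22),
                         V_min = c(1, 1), V_max = c(5, 5), V_AD_max = 7,
                         S = 60, variant = c("BM", "CM", "IM"),
                         alpha_TC = 0, alpha_AD = 0, mu = c(0, 0),
                         enforce_volume_on_fixed = TRUE,
                         volume_min_form = c("conditional", "printed")) {
  variant <- match.arg(variant)
  volume_min_form <- match.arg(volume_min_form)
  r <- rep_len(as.numeric(r), 2)
  V_min <- rep_len(as.numeric(V_min), 2)
  V_max <- rep_len(as.numeric(V_max), 2)
  mu <- rep_len(as.numeric(mu), 2)
  vals <- c(p_TC, p_AD, r, V_min, S, alpha_TC, alpha_AD, mu)
  stop_if(any(!is.finite(vals)) || any(vals < 0),
          "counts, caps and times must be finite and non-negative")
  stop_if(any(is.na(c(V_max, V_AD_max))) || any(c(V_max, V_AD_max) < 0),
          "volume maxima must be non-negative (Inf disables them)")
  stop_if(any(V_min > V_max), "V_min must not exceed V_max")
  structure(list(p_TC = p_TC, p_AD = p_AD, r = r,
                 V_min = V_min, V_max = V_max, V_AD_max = V_AD_max,
                 S = S, variant = variant,
                 alpha_TC = alpha_TC, alpha_AD = alpha_AD, mu = mu,
                 enforce_volume_on_fixed = isTRUE(enforce_volume_on_fixed),
                 volume_min_form = volume_min_form),
            class = "tn_config")
}

#' @export
print.tn_config <- function(x, ...) {
  cat("Model configuration (variant ", x$variant, ")\n", sep = "")
  cat("  budgets: p_TC=", x$p_TC, ", p_AD=", x$p_AD,
      "; per-type caps r=(", x$r[1], ",", x$r[2], ")\n", sep = "")
  cat("  volume: V_min=(", x$V_min[1], ",", x$V_min[2], "), V_max=(",
      x$V_max[1], ",", x$V_max[2], "), V_AD_max=", x$V_AD_max, "\n", sep = "")
  cat("  time standard S=", x$S, " min; volume_min_form=",
      x$volume_min_form, "\n", sep = "")
  if (x$variant == "IM")
    cat("  expansion: alpha_TC=", x$alpha_TC, ", alpha_AD=", x$alpha_AD,
        ", mu=(", x$mu[1], ",", x$mu[2], ")\n", sep = "")
  invisible(x)
}

#' Read a model configuration from YAML
#'
#' Keys mirror the arguments of [model_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  extra <- setdiff(names(y), known)
  stop_if(length(extra) > 0,
          "unknown configuration key(s): ", paste(extra, collapse = ", "))
  do.call(model_config, y)
}
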