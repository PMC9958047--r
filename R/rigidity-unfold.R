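#' Map a hydrogen-bond energy cutoff to a temperature
#'
#' Linear conversion `T = -(20 K / (kcal/mol)) * E_cut + 300 K`, so the
#' default dilution schedule from -0.1 to -6.0 kcal/mol corresponds to
#' heating from 302 K to 420 K in 2 K steps.
#'
#' @param e_cut energy cutoff(s) in kcal/mol.
#' @return Temperature(s) in kelvin.
#' @export
ecut_to_temperature <- function(e_cut) -20 * e_cut + 300

#' Default thermal-unfolding dilution schedule
#'
#' `E_cut` from -0.1 to -6.0 kcal/mol in steps of 0.1 (60 steps, endpoints
#' inclusive).
#' @return Numeric vector of cutoffs (decreasing).
#' @export
default_schedule <- function() round(seq(-0.1, -6.0, by = -0.1), 10)

#' Thermal unfolding by constraint dilution
#'
#' Removes hydrogen-bond and salt-bridge bars with `E_HB > E_cut` at each
#' step of a decreasing cutoff schedule (covalent bars and hydrophobic
#' tethers are retained throughout), recomputes the rigid-cluster
#' decomposition, and records the cluster configuration entropy and the
#' mapped temperature. The set of present bars at step k+1 is a subset of
#' that at step k, so the largest rigid cluster is non-increasing.
#'
#' @param network a [constraint_network()].
#' @param schedule decreasing vector of `E_cut` values (kcal/mol);
#'   default [default_schedule()].
#' @param keep_decompositions keep per-step decompositions (default FALSE).
#' @return An `unfolding_trajectory`: data.frame with columns `e_cut`,
#'   `T_K`, `h_type2`, `largest_fraction`, `n_clusters`, `n_bars_present`;
#'   decompositions (if kept) in attribute `decompositions`.
#' @export
dilute <- function(network, schedule = default_schedule(),
                   keep_decompositions = FALSE) {
  tl_assert(inherits(network, "constraint_network"), "not a constraint_network")
  tl_assert(length(schedule) >= 1, "empty dilution schedule")
  tl_assert(all(diff(schedule) < 0) || length(schedule) == 1,
            "schedule must be strictly decreasing")
  bars <- network$bars
  dilutable <- bars$type %in% c("hbond", "saltbridge")
  steps <- vector("list", length(schedule))
  decomps <- if (keep_decompositions) vector("list", length(schedule))
  prev_keep <- NULL; prev_dec <- NULL
  for (k in seq_along(schedule)) {
    ec <- schedule[k]
    keep <- !dilutable | (bars$e_hb <= ec + 1e-12)
    if (!is.null(prev_keep) && identical(keep, prev_keep)) {
      dec <- prev_dec  # bar set unchanged: decomposition unchanged
    } else {
      sub <- constraint_network(network$n_bodies, bars[keep, , drop = FALSE])
      dec <- pebble_game(sub)
    }
    prev_keep <- keep; prev_dec <- dec
    if (keep_decompositions) decomps[[k]] <- dec
    steps[[k]] <- data.frame(
      e_cut = ec, T_K = ecut_to_temperature(ec),
      h_type2 = cluster_entropy(dec),
      largest_fraction = dec$largest_fraction,
      n_clusters = length(dec$sizes),
      n_bars_present = sum(bars$mult[keep]))
  }
  traj <- do.call(rbind, steps)
  class(traj) <- c("unfolding_trajectory", "data.frame")
  if (keep_decompositions) attr(traj, "decompositions") <- decomps
  traj
}

#' Phase transition temperature from an unfolding trajectory
#'
#' Fits a double sigmoid to the `H_type2` versus `T(E_cut)` curve
#' ([fit_double_sigmoid()]) and applies the transition selection rule
#' ([select_tp()]): the transition with the largest slope, except that the
#' second (higher-temperature) transition is chosen when the experimental
#' denaturation temperature exceeds 50 degrees C.
#'
#' @param trajectory an `unfolding_trajectory` from [dilute()].
#' @param td optional denaturation temperature in degrees C.
#' @return A `tp_result`: list with `tp_K`, `tp_C`, `transitions`,
#'   `rule_applied` and the underlying `fit`.
#' @export
compute_tp <- function(trajectory, td = NULL) {
  tl_assert(inherits(trajectory, "data.frame") &&
              all(c("h_type2", "T_K") %in% names(trajectory)),
            "trajectory must have columns h_type2 and T_K")
  fit <- fit_double_sigmoid(trajectory$h_type2, trajectory$T_K)
  if (!fit$converged)
    tl_stop("no resolvable transition in H_type2 trajectory (flat curve?)")
  sel <- select_tp(fit, td)
  structure(list(tp_K = sel$tp, tp_C = sel$tp - 273.15,
                 transitions = fit$transitions,
                 rule_applied = sel$rule, fit = fit),
            class = "tp_result")
}

#' @export
print.tp_result <- function(x, ...) {
  cat(sprintf("Tp = %.1f K (%.1f degC), rule: %s\n",
              x$tp_K, x$tp_C, x$rule_applied))
  invisible(x)
}

#' Aggregate phase transition temperatures over replicates
#'
#' Mirrors the replicate protocol in which each structure is analysed on
#' several independently generated conformational ensembles: arithmetic
#' mean and standard error of the mean (SEM = SD/sqrt(n); undefined for a
#' single replicate).
#'
#' @param tp numeric vector of per-replicate Tp values (any unit).
#' @return list with `mean`, `sem` (NA when n = 1), `n`.
#' @export
aggregate_replicates <- function(tp) {
  tl_assert(length(tp) >= 1, "empty replicate list")
  n <- length(tp)
  list(mean = mean(tp),
       sem = if (n > 1) sd(tp) / sqrt(n) else NA_real_,
       n = n)
}
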