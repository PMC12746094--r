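# Plan finalization: monitor-unit feasibility and plan normalization.

#' Enforce minimum/maximum monitor-unit limits
#'
#' Spots with weight below `mu_min` are removed from the support, then one
#' re-optimization of the stage-final scalarized problem is run on the
#' reduced support with box constraints `mu_min <= w <= mu_max` and all
#' hard constraints re-imposed (a single constraint-restoration re-solve).
#' Final weights are either 0 (removed) or inside the MU box.
#'
#' @param plan a `protonarc_plan`.
#' @param dij the dose-influence set the plan was optimized on.
#' @param phantom the phantom.
#' @param wishlist the wish-list (hard constraints re-imposed).
#' @param mu_min,mu_max MU limits, `0 < mu_min <= mu_max`.
#' @param ... passed to [solve_surrogate()].
#' @return the finalized `protonarc_plan` (removed spots carry weight 0);
#'   fields `mu_min`, `mu_max` recorded.
#' @export
enforce_mu_limits <- function(plan, dij, phantom, wishlist,
                              mu_min = 0.02, mu_max = 500, ...) {
  if (!(mu_min > 0 && mu_min <= mu_max))
    stop_protonarc("need 0 < mu_min <= mu_max", "protonarc_spec_error")
  w <- plan$weights
  keep_ids <- as.integer(names(w)[w >= mu_min])
  if (!length(keep_ids))
    stop_protonarc("MU restoration infeasible: no spot reaches mu_min",
                   "protonarc_infeasible")
  res <- solve_surrogate(dij, phantom, wishlist, support = keep_ids,
                         spot_lower = mu_min, spot_upper = mu_max, ...)
  new_w <- stats::setNames(numeric(length(w)), names(w))
  new_w[names(res$weights)] <- res$weights
  plan$weights <- new_w
  plan$mu_min <- mu_min
  plan$mu_max <- mu_max
  plan$selected_els <- dplyr::distinct(
    plan$spots[plan$weights > 1e-9, ], field_index, el_index)
  if (!is.null(plan$achieved)) {
    wfull <- plan_weights_for(plan, dij)
    plan$achieved$achieved <- vapply(seq_len(nrow(plan$achieved)), function(k)
      metric_value(dij, phantom, plan$achieved$structure[k],
                   plan$achieved$metric[k], wfull,
                   robust = isTRUE(plan$achieved$robust[k])), numeric(1))
  }
  plan
}

#' Normalize a plan to robust target coverage
#'
#' All spot weights are scaled by
#' `s = 0.95 * prescription / D98%(VWmin over the high-dose target)` so
#' that, after normalization, the D98% of the 21-scenario voxel-wise
#' minimum dose over the high-dose target equals 95 percent of the
#' prescription (exact by dose linearity). MU-limit compliance is
#' re-checked after scaling; violations warn rather than loop.
#'
#' @param plan a `protonarc_plan`.
#' @param dij the dose-influence set (all scenarios).
#' @param phantom the phantom.
#' @param prescription_gy prescription dose (Gy_RBE).
#' @return the normalized plan; field `normalization_scale` carries the
#'   cumulative scale factor.
#' @export
normalize_plan <- function(plan, dij, phantom, prescription_gy = 70) {
  th <- structures_by_role(phantom, "target_high")
  if (!length(th) || !any(phantom$masks[[th[1]]]))
    stop_protonarc("phantom has no (non-empty) high-dose target",
                   "protonarc_spec_error")
  w <- plan_weights_for(plan, dij)
  doses <- lapply(seq_len(nrow(dij$scenarios)), function(s) dose_vector(dij, w, s))
  vwmin <- voxelwise_aggregate(doses, "min")
  d98 <- dvh_metric(vwmin, phantom$masks[[th[1]]], "D98%")
  if (d98 <= 0)
    stop_protonarc("normalization undefined: D98%(VWmin) of the target is zero",
                   "protonarc_spec_error")
  s <- 0.95 * prescription_gy / d98
  plan$weights <- plan$weights * s
  plan$normalization_scale <- (plan$normalization_scale %||% 1) * s
  if (!is.null(plan$mu_min)) {
    nz <- plan$weights[plan$weights > 1e-9]
    if (any(nz < plan$mu_min - 1e-9) || any(nz > plan$mu_max + 1e-9))
      warning(sprintf(
        "normalization scale %.4f pushed %d spot(s) outside the MU box",
        s, sum(nz < plan$mu_min - 1e-9 | nz > plan$mu_max + 1e-9)))
  }
  if (!is.null(plan$achieved)) plan$achieved$achieved <- plan$achieved$achieved * s
  plan
}
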