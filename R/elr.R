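# Energy-layer reduction (ELR) for discrete proton arc therapy: group
# regularization over energy layers trades the number of delivered layers
# against plan quality via a single coefficient.

#' Group candidate spots by energy layer
#'
#' One group per distinct (field, energy-layer) pair; the groups partition
#' the candidate spot set.
#'
#' @param spots spot tibble.
#' @return tibble with `group_id`, `field_index`, `el_index`, `n_members`,
#'   and a list-column `member_ids`; attribute `"membership"` maps each spot
#'   row to its group id.
#' @export
build_el_groups <- function(spots) {
  if (!nrow(spots))
    stop_protonarc("no spots to group", "protonarc_spec_error")
  key <- paste(spots$field_index, spots$el_index, sep = "/")
  lev <- unique(key)
  membership <- match(key, lev)
  g <- tibble::tibble(group_id = seq_along(lev),
                      field_index = spots$field_index[match(lev, key)],
                      el_index = spots$el_index[match(lev, key)],
                      n_members = tabulate(membership, length(lev)),
                      member_ids = split(spots$id, membership)[as.character(seq_along(lev))])
  attr(g, "membership") <- membership
  g
}

#' Reduce the energy-layer set by group regularization
#'
#' Solves the scalarized wish-list surrogate plus the group penalty
#' `lambda * sum_g sqrt(|g|) * ||w_g||_2` (classical group lasso over
#' energy layers) subject to all hard constraints. An energy layer is
#' selected iff its group weight norm exceeds `1e-3` times the largest
#' group norm; all spots of unselected layers are removed from the problem
#' passed downstream (SISS, then MCO).
#'
#' @param dij a `protonarc_dij`.
#' @param phantom the phantom.
#' @param wishlist a `protonarc_wishlist`.
#' @param groups from [build_el_groups()] (defaults to grouping
#'   `dij$spots`).
#' @param lambda group-penalty coefficient (>= 0).
#' @param activity_rel selection threshold relative to the max group norm.
#' @param ... passed to [solve_surrogate()].
#' @return list with `selected_els` (tibble field/el), `selected_ids`
#'   (spot ids surviving), `group_norms`, `objective` (surrogate objective
#'   of the penalized solution, penalty excluded) and `lambda`.
#' @export
reduce_energy_layers <- function(dij, phantom, wishlist,
                                 groups = build_el_groups(dij$spots),
                                 lambda = 0, activity_rel = 1e-3, ...) {
  if (lambda < 0)
    stop_protonarc("lambda must be >= 0", "protonarc_spec_error")
  membership <- attr(groups, "membership")
  res <- solve_surrogate(dij, phantom, wishlist, groups = membership,
                         lambda = lambda, ...)
  norms <- res$group_norms$norm2
  sel <- norms > activity_rel * max(norms, 1e-12)
  list(selected_els = groups[sel, c("group_id", "field_index", "el_index")],
       selected_ids = sort(unlist(groups$member_ids[sel], use.names = FALSE)),
       group_norms = tibble::tibble(group_id = groups$group_id,
                                    field_index = groups$field_index,
                                    el_index = groups$el_index, norm2 = norms),
       objective = res$objective, lambda = lambda)
}

#' Tune the ELR coefficient to a target energy-layer count
#'
#' Bisection on log-lambda until the selected EL count is within 5 percent
#' of `target_mean_els` (or the bracket is exhausted). Deterministic for
#' fixed inputs.
#'
#' @inheritParams reduce_energy_layers
#' @param target_mean_els target number of selected energy layers.
#' @param bracket lambda bracket (log bisection).
#' @param max_iter bisection iterations.
#' @return the tuned lambda (attributes: `"el_count"`, `"result"`).
#' @export
tune_lambda <- function(dij, phantom, wishlist,
                        groups = build_el_groups(dij$spots),
                        target_mean_els, bracket = c(1e-4, 10),
                        max_iter = 25, ...) {
  count_at <- function(lam) nrow(reduce_energy_layers(
    dij, phantom, wishlist, groups, lambda = lam, ...)$selected_els)
  lo <- log(bracket[1]); hi <- log(bracket[2])
  n_lo <- count_at(exp(lo)); n_hi <- count_at(exp(hi))
  if (target_mean_els > n_lo || target_mean_els < n_hi)
    stop_protonarc(sprintf(
      "target EL count %d outside attainable range [%d, %d] on bracket [%g, %g]",
      target_mean_els, n_hi, n_lo, bracket[1], bracket[2]),
      "protonarc_bracket_error")
  if (target_mean_els == n_lo) lam <- exp(lo)
  else if (target_mean_els == n_hi) lam <- exp(hi)
  else {
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      nc <- count_at(exp(mid))
      if (abs(nc - target_mean_els) <= 0.05 * target_mean_els) { lam <- exp(mid); break }
      if (nc > target_mean_els) lo <- mid else hi <- mid
      lam <- exp((lo + hi) / 2)
    }
  }
  res <- reduce_energy_layers(dij, phantom, wishlist, groups, lambda = lam, ...)
  structure(lam, el_count = nrow(res$selected_els), result = res)
}
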