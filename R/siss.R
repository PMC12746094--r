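# Sparsity-induced spot selection (SISS): phase 1 of the optimizer — an
# L1-penalized solve of the scalarized wish-list surrogate that picks the
# high-weight spot support before the lexicographic MCO.

#' Select the high-weight spot support
#'
#' Solves the scalarized wish-list surrogate with an added L1 term
#' (`coefficient * sum(w)`, the exact L1 penalty for nonnegative weights)
#' subject to all hard constraints, and returns the spots whose weight
#' exceeds the activity threshold (`1e-3` times the maximum weight). When
#' `target_count` is given, the coefficient is bisected on a log scale
#' until the selected count is within 5 percent of the target.
#'
#' @param dij a `protonarc_dij`.
#' @param phantom the phantom.
#' @param wishlist a `protonarc_wishlist`.
#' @param sparsity_coefficient L1 coefficient (>= 0).
#' @param target_count optional target support size.
#' @param bracket log-bisection bracket for the coefficient.
#' @param activity_rel activity threshold relative to the max weight.
#' @param ... passed to [solve_surrogate()].
#' @return integer vector of selected spot ids (attribute `"coefficient"`
#'   carries the coefficient actually used).
#' @export
select_spots <- function(dij, phantom, wishlist, sparsity_coefficient = 0,
                         target_count = NULL, bracket = c(1e-4, 10),
                         activity_rel = 1e-3, ...) {
  if (sparsity_coefficient < 0)
    stop_protonarc("sparsity coefficient must be >= 0", "protonarc_spec_error")
  pick <- function(coeff) {
    res <- solve_surrogate(dij, phantom, wishlist, l1 = coeff, ...)
    w <- res$weights
    ids <- dij$spots$id[w > activity_rel * max(w, 1e-12)]
    structure(ids, coefficient = coeff)
  }
  if (is.null(target_count)) return(pick(sparsity_coefficient))
  lo <- log(bracket[1]); hi <- log(bracket[2])
  n_lo <- length(pick(exp(lo))); n_hi <- length(pick(exp(hi)))
  if (target_count > n_lo || target_count < n_hi)
    stop_protonarc(sprintf(
      "target count %d outside attainable bracket [%d, %d] for coefficients [%g, %g]",
      target_count, n_hi, n_lo, bracket[1], bracket[2]),
      "protonarc_bracket_error")
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    sel <- pick(exp(mid))
    if (abs(length(sel) - target_count) <= 0.05 * target_count) return(sel)
    if (length(sel) > target_count) lo <- mid else hi <- mid
  }
  sel
}
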