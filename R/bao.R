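# Beam-angle optimization: total-beam-space solve over 72 equiangular
# candidates with beam-level group sparsification, then top-N beam pick.

#' Optimize patient-tailored beam angles
#'
#' Builds a (coarse) dose-influence set for 72 coplanar equiangular
#' candidate beams, solves the scalarized wish-list surrogate with a
#' beam-level group-lasso penalty (all spots of one beam form a group),
#' ranks beams by their group weight norm, and returns the `n_beams`
#' highest. Ties are broken towards the smaller gantry angle. The coarse
#' candidate resolution (default twice the planning spacings) is a
#' fidelity/runtime knob; the final plan on the selected beams uses full
#' resolution.
#'
#' @param phantom the phantom.
#' @param wishlist a `protonarc_wishlist`.
#' @param n_beams number of beams to select (1..72).
#' @param lambda_beam beam-group penalty coefficient.
#' @param lateral_spacing_mm,el_spacing_wet_mm coarse candidate spacings.
#' @param margin_mm target margin (mm).
#' @param scenarios scenario set for the candidate solve (nominal-only by
#'   default: a runtime/fidelity trade-off for the 72-beam problem).
#' @param model [beam_model()] parameters.
#' @param ... passed to [solve_surrogate()].
#' @return beam tibble (`field_index` renumbered 1..n); attributes
#'   `"candidate_norms"` (per-candidate group norms tibble) and
#'   `"lambda_beam"`.
#' @export
optimize_beam_angles <- function(phantom, wishlist, n_beams, lambda_beam = 0.02,
                                 lateral_spacing_mm = 12, el_spacing_wet_mm = 12,
                                 margin_mm = 5,
                                 scenarios = build_scenarios(mode = "nominal_only"),
                                 model = beam_model(), ...) {
  cand <- make_beam_set("bao_candidates")
  if (n_beams < 1 || n_beams > nrow(cand))
    stop_protonarc(sprintf("n_beams must be in 1..%d", nrow(cand)),
                   "protonarc_spec_error")
  spots <- candidate_spots(phantom, cand, lateral_spacing_mm, el_spacing_wet_mm,
                           margin_mm, model)
  dij <- compute_dij(phantom, spots, scenarios, model = model)
  membership <- match(dij$spots$field_index, cand$field_index)
  res <- solve_surrogate(dij, phantom, wishlist, groups = membership,
                         lambda = lambda_beam, ...)
  norms <- numeric(nrow(cand))
  norms[seq_len(nrow(res$group_norms))] <- res$group_norms$norm2
  ord <- order(-norms, cand$gantry_deg)
  sel <- sort(ord[seq_len(n_beams)])
  out <- cand[sel, ]
  out$field_index <- seq_len(nrow(out))
  attr(out, "candidate_norms") <- tibble::tibble(
    gantry_deg = cand$gantry_deg, norm2 = norms, selected = seq_len(nrow(cand)) %in% sel)
  attr(out, "lambda_beam") <- lambda_beam
  out
}

#' Plan on a fixed beam set (with or without range shifters)
#'
#' Runs the full downstream pipeline (candidate spots, blocking, SISS,
#' lexicographic MCO, MU finalization, normalization) on the given beams,
#' with every field sharing the `with_rs` flag. Callers comparing the
#' with/without range-shifter pair keep the better plan (summed NTCP, then
#' integral dose — see [run_mode()]).
#'
#' @param phantom the phantom.
#' @param beams beam tibble.
#' @param wishlist a `protonarc_wishlist`.
#' @param with_rs logical: range shifter (34 mm WET by default) in all
#'   fields.
#' @param config a [pa_config()] list.
#' @return list with `plan`, `report`, `dij` (see [run_mode()]).
#' @export
plan_with_selected_beams <- function(phantom, beams, wishlist, with_rs = FALSE,
                                     config = pa_config()) {
  if (!nrow(beams))
    stop_protonarc("empty beam set", "protonarc_spec_error")
  beams$range_shifter <- with_rs
  plan_pipeline(phantom, beams, wishlist, config,
                mode = sprintf("fixed%d%s", nrow(beams), if (with_rs) "_rs" else ""),
                elr = FALSE)
}
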