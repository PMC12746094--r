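# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_protonarc <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "protonarc_error"), ...)
}

utils::globalVariables(c(
  "field_index", "el_index", "gantry_deg", "couch_deg", "range_shifter",
  "rs_wet_mm", "id", "range_mm", "lat1_mm", "lat2_mm", "priority",
  "structure", "metric", "value", "weight", "group_id", "norm2", "label",
  "spot_id", "mode", "phantom", "achieved", "goal", "bound", "robust",
  "n_members", "el_count", "difference", "median_diff", "p_value", "model"
))
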