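# Shared, lazily-computed planning artifacts. The full robust cs4 plan on
# the default phantom is expensive (minutes), so the acceptance-grade
# pipeline run is computed once per test session and reused.

.plan_cache <- new.env(parent = emptyenv())

cached_default_phantom <- function() {
  if (is.null(.plan_cache$phantom))
    .plan_cache$phantom <- generate_phantom(default_phantom_spec(), seed = 1)
  .plan_cache$phantom
}

# Full 21-scenario cs4 pipeline on the default quasi-2D phantom.
cached_cs4 <- function() {
  if (is.null(.plan_cache$cs4))
    .plan_cache$cs4 <- run_mode(cached_default_phantom(), "cs4", pa_config())
  .plan_cache$cs4
}

# Coarse nominal-scenario settings for multi-mode study tests: smaller
# phantom voxels are traded for wall time, not for different physics.
fast_config <- function(...) {
  args <- list(...)
  defaults <- list(lateral_spacing_mm = 12, el_spacing_wet_mm = 12,
                   scenarios = build_scenarios(mode = "nominal_only"))
  do.call(pa_config, utils::modifyList(defaults, args))
}

fast_phantom <- function(seed = 1) {
  generate_phantom(default_phantom_spec(spacing_mm = 6), seed = seed)
}
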