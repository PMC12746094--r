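# Robustness scenario set: setup shifts and range (density) scaling.

#' Build the robustness scenario set
#'
#' Scenario-based robust optimization uses 21 error scenarios: the nominal
#' scenario, range undershoot/overshoot without setup error, setup shifts of
#' `setup_mm` along each axis in both directions without range error, and the
#' same six shifts combined with undershoot and with overshoot. Range
#' undershoot is realized as a global density scaling by (1 + range_pct/100)
#' (denser tissue, shallower Bragg peak); overshoot by (1 - range_pct/100).
#'
#' @param setup_mm setup error magnitude (mm, >= 0).
#' @param range_pct range error magnitude (percent, >= 0).
#' @param mode `"robust"` (21 scenarios) or `"nominal_only"` (1 scenario).
#' @return a tibble with columns `label`, `sx_mm`, `sy_mm`, `sz_mm`,
#'   `range_scale`; the nominal scenario is always first.
#' @export
#' @examples
#' nrow(build_scenarios(3, 3))            # 21
#' build_scenarios(mode = "nominal_only") # 1 row
build_scenarios <- function(setup_mm = 3, range_pct = 3, mode = c("robust", "nominal_only")) {
  mode <- match.arg(mode)
  if (setup_mm < 0 || range_pct < 0)
    stop_protonarc("setup_mm and range_pct must be non-negative", "protonarc_spec_error")
  nominal <- tibble::tibble(label = "nominal", sx_mm = 0, sy_mm = 0, sz_mm = 0,
                            range_scale = 1)
  if (mode == "nominal_only") return(nominal)
  under <- 1 + range_pct / 100
  over <- 1 - range_pct / 100
  shifts <- rbind(c(setup_mm, 0, 0), c(-setup_mm, 0, 0),
                  c(0, setup_mm, 0), c(0, -setup_mm, 0),
                  c(0, 0, setup_mm), c(0, 0, -setup_mm))
  shift_block <- function(scale, tag) tibble::tibble(
    label = paste0("setup_", c("px", "mx", "py", "my", "pz", "mz"), tag),
    sx_mm = shifts[, 1], sy_mm = shifts[, 2], sz_mm = shifts[, 3],
    range_scale = scale)
  dplyr::bind_rows(
    nominal,
    tibble::tibble(label = c("undershoot", "overshoot"),
                   sx_mm = 0, sy_mm = 0, sz_mm = 0,
                   range_scale = c(under, over)),
    shift_block(1, ""),
    shift_block(under, "_under"),
    shift_block(over, "_over"))
}

#' Voxel-wise extreme over scenario dose distributions
#'
#' @param doses list of dose rasters (equal-shaped arrays or vectors), one
#'   per scenario.
#' @param which `"min"` or `"max"`.
#' @return the element-wise extreme, same shape as the inputs.
#' @export
voxelwise_aggregate <- function(doses, which = c("min", "max")) {
  which <- match.arg(which)
  dims <- lapply(doses, function(d) dim(d) %||% length(d))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop_protonarc("dose rasters do not share a common shape", "protonarc_format_error")
  Reduce(if (which == "min") pmin else pmax, doses)
}
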