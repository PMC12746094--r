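# Pipeline orchestration: one shared optimizer, four delivery approaches.
#
# pat36     ELR -> SISS -> MCO -> finalize
# utopia36  identical pipeline with ELR skipped (dosimetric benchmark)
# cs4/cs6   printed class-solution beams + range-shifter rules
# bao6/8/10 beam-angle optimization, then both range-shifter variants,
#           keeping the better plan
# All modes run under a single wish-list instance (bias-free comparison).

#' Pipeline configuration
#'
#' Bundles the knobs of a planning run: spot spacings, the dose model, the
#' robustness scenario set, sparsification coefficients, MU limits and the
#' prescription. Defaults are the package's desk-scale study conditions.
#'
#' @param lateral_spacing_mm,el_spacing_wet_mm,margin_mm spot generation.
#' @param model [beam_model()] parameters.
#' @param scenarios scenario tibble for robust optimization/evaluation.
#' @param siss_coeff L1 coefficient of the SISS phase.
#' @param elr_lambda group-penalty coefficient of the ELR phase (pat36).
#' @param elr_target optional target EL count; when set, overrides
#'   `elr_lambda` via [tune_lambda()].
#' @param bao_lambda,bao_lateral_mm,bao_el_mm beam-angle-optimization
#'   candidate-solve settings (coarse resolution).
#' @param mu_min,mu_max monitor-unit limits.
#' @param prescription_gy high-dose target prescription.
#' @param delta lexicographic slack factor.
#' @param ntcp_models NTCP model list (NULL = load the shipped set on
#'   demand).
#' @param block apply spot blocking through `blocking`-role structures.
#' @return a config list.
#' @export
pa_config <- function(lateral_spacing_mm = 6, el_spacing_wet_mm = 6,
                      margin_mm = 5, model = beam_model(),
                      scenarios = build_scenarios(3, 3, "robust"),
                      siss_coeff = 0.005, elr_lambda = 0.05,
                      elr_target = NULL, bao_lambda = 0.02,
                      bao_lateral_mm = 12, bao_el_mm = 12,
                      mu_min = 0.02, mu_max = 500, prescription_gy = 70,
                      delta = 0.03, ntcp_models = NULL, block = TRUE) {
  as.list(environment())
}

# Pick the better of a with/without range-shifter plan pair: lower summed
# NTCP over all grades; ties broken by lower integral dose.
select_rs_variant <- function(variants) {
  score <- vapply(variants, function(v) {
    s <- v$report$summary
    ntcp_cols <- grep("^summed_ntcp_", names(s), value = TRUE)
    sum(unlist(s[ntcp_cols])) * 1e6 + s$integral_dose_gy_l
  }, numeric(1))
  which.min(score)
}

# Shared downstream pipeline on a fixed beam set.
plan_pipeline <- function(phantom, beams, wishlist, config, mode, elr = FALSE) {
  spots <- candidate_spots(phantom, beams, config$lateral_spacing_mm,
                           config$el_spacing_wet_mm, config$margin_mm,
                           config$model, block = config$block)
  if (!nrow(spots))
    stop_protonarc("no candidate spots after blocking", "protonarc_spec_error")
  dij <- compute_dij(phantom, spots, config$scenarios, model = config$model)
  elr_info <- NULL
  if (elr) {
    groups <- build_el_groups(dij$spots)
    if (!is.null(config$elr_target)) {
      lam <- tune_lambda(dij, phantom, wishlist, groups,
                         target_mean_els = config$elr_target)
      elr_info <- attr(lam, "result")
    } else {
      elr_info <- reduce_energy_layers(dij, phantom, wishlist, groups,
                                       lambda = config$elr_lambda)
    }
    dij <- dij_subset(dij, elr_info$selected_ids)
  }
  support <- select_spots(dij, phantom, wishlist,
                          sparsity_coefficient = config$siss_coeff)
  plan <- solve_lexicographic(dij, phantom, wishlist, support = support,
                              delta = config$delta, mode = mode)
  dij_s <- dij_subset(dij, support)
  plan <- enforce_mu_limits(plan, dij_s, phantom, wishlist,
                            mu_min = config$mu_min, mu_max = config$mu_max)
  plan <- normalize_plan(plan, dij_s, phantom,
                         prescription_gy = config$prescription_gy)
  plan$mode <- mode
  if (!is.null(elr_info)) {
    plan$elr_lambda <- elr_info$lambda
    plan$elr_selected_els <- elr_info$selected_els
  }
  models <- config$ntcp_models %||% load_ntcp_models()
  report <- evaluate_plan(plan, dij_s, phantom, ntcp_models = models)
  list(plan = plan, report = report, dij = dij_s)
}

#' Run one planning mode end-to-end
#'
#' @param phantom the phantom.
#' @param mode one of `"pat36"`, `"utopia36"`, `"cs4"`, `"cs6"`, `"bao6"`,
#'   `"bao8"`, `"bao10"`.
#' @param config a [pa_config()] list.
#' @param wishlist the shared wish-list (default: the shipped default).
#' @return list with `plan` (`protonarc_plan`), `report`
#'   (`protonarc_eval`), and `dij` (the support-restricted dose influence).
#' @export
run_mode <- function(phantom, mode, config = pa_config(),
                     wishlist = parse_wishlist(default_wishlist())) {
  known <- c("pat36", "utopia36", "cs4", "cs6", "bao6", "bao8", "bao10")
  if (!mode %in% known)
    stop_protonarc(sprintf("unknown mode '%s'", mode), "protonarc_spec_error")
  if (mode %in% c("pat36", "utopia36", "cs4", "cs6")) {
    beams <- make_beam_set(if (mode %in% c("pat36", "utopia36")) "pat36" else mode)
    return(plan_pipeline(phantom, beams, wishlist, config, mode,
                         elr = mode == "pat36"))
  }
  n_beams <- as.integer(sub("bao", "", mode))
  beams <- optimize_beam_angles(phantom, wishlist, n_beams,
                                lambda_beam = config$bao_lambda,
                                lateral_spacing_mm = config$bao_lateral_mm,
                                el_spacing_wet_mm = config$bao_el_mm,
                                margin_mm = config$margin_mm,
                                model = config$model)
  variants <- lapply(c(FALSE, TRUE), function(rs)
    plan_with_selected_beams(phantom, beams, wishlist, with_rs = rs,
                             config = config))
  best <- variants[[select_rs_variant(variants)]]
  best$plan$mode <- mode
  best$report$summary$mode <- mode
  best$plan$bao_candidates <- attr(beams, "candidate_norms")
  best
}

#' Run a seeded multi-phantom comparison study
#'
#' Generates `length(seeds)` phantoms from seeded perturbations of the
#' phantom spec, runs every requested mode on each under one shared
#' wish-list, and emits a long metric table plus paired Wilcoxon
#' comparisons for every mode pair. Per-phantom failures are isolated and
#' logged; the study continues.
#'
#' @param seeds integer vector of phantom seeds (>= 5 for meaningful
#'   statistics).
#' @param modes character vector of [run_mode()] modes.
#' @param config a [pa_config()] list.
#' @param wishlist the shared wish-list.
#' @param spec phantom spec (default [default_phantom_spec()]).
#' @param out_dir optional directory: writes `metrics.csv`, `compare.csv`
#'   and per-phantom plan JSONs.
#' @return list with `metrics` (long tibble: phantom, mode, metric,
#'   value), `comparisons` (tibble over mode pairs), `failures`.
#' @export
run_study <- function(seeds, modes, config = pa_config(),
                      wishlist = parse_wishlist(default_wishlist()),
                      spec = default_phantom_spec(), out_dir = NULL) {
  metrics <- list()
  failures <- list()
  for (sd in seeds) {
    ph <- generate_phantom(spec, seed = sd)
    for (md in modes) {
      res <- tryCatch(run_mode(ph, md, config, wishlist), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(phantom = sd, mode = md, error = conditionMessage(res))
        next
      }
      tv <- tidy(res$report)
      s <- res$report$summary
      extra <- tibble::tibble(
        structure = "plan", role = "summary",
        metric = setdiff(names(s), c("mode", "wishlist_digest")),
        value = as.numeric(s[setdiff(names(s), c("mode", "wishlist_digest"))]))
      m <- dplyr::bind_rows(tv, extra)
      m$phantom <- sd
      m$mode <- md
      m$wishlist_digest <- s$wishlist_digest
      metrics[[length(metrics) + 1L]] <- m
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, as.character(sd), md)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_plan(res$plan, file.path(d, "plan.json"))
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  comparisons <- NULL
  if (length(modes) >= 2 && nrow(metrics)) {
    key_metrics <- c("dmean_gy", "ntcp_g2", "ntcp_g3", "integral_dose_gy_l",
                     grep("^summed_ntcp_", unique(metrics$metric), value = TRUE))
    mm <- metrics[metrics$metric %in% key_metrics, ]
    mm$metric <- paste(mm$structure, mm$metric, sep = ".")
    pairs <- utils::combn(modes, 2, simplify = FALSE)
    comparisons <- dplyr::bind_rows(lapply(pairs, function(p) {
      a <- mm[mm$mode == p[1], c("phantom", "metric", "value")]
      b <- mm[mm$mode == p[2], c("phantom", "metric", "value")]
      shared <- intersect(paste(a$phantom, a$metric), paste(b$phantom, b$metric))
      a <- a[paste(a$phantom, a$metric) %in% shared, ]
      b <- b[paste(b$phantom, b$metric) %in% shared, ]
      if (!nrow(a)) return(NULL)
      cmp <- compare_plans(a, b)
      cmp$mode_a <- p[1]
      cmp$mode_b <- p[2]
      cmp
    }))
  }
  out <- list(metrics = metrics, comparisons = comparisons,
              failures = dplyr::bind_rows(failures))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "compare.csv"),
                       row.names = FALSE)
  }
  out
}

#' Write / read a plan as JSON
#'
#' @param plan a `protonarc_plan`.
#' @param path JSON file path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(list(
    mode = plan$mode,
    weights = unname(Map(function(id, w) list(spot_id = as.integer(id), mu = w),
                         names(plan$weights), unname(plan$weights))),
    achieved = as.data.frame(plan$achieved),
    beams = as.data.frame(plan$beams),
    selected_els = as.data.frame(plan$selected_els),
    mu_min = plan$mu_min, mu_max = plan$mu_max,
    normalization_scale = plan$normalization_scale,
    wishlist_digest = plan$wishlist_digest
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
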