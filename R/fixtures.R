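# Deterministic toy problems with oracle-checkable solutions — the fixture
# layer the optimization tests consume. Oracles ship as code (brute-force
# enumeration / grid search), never as frozen constants, so drift between
# solver and oracle is detectable.

# A minimal phantom over an (nvox, 1, 1) grid: every voxel is 1 mm^3 of
# water; masks are logical vectors over the voxels.
toy_phantom <- function(nvox, masks, roles) {
  grid <- grid_spec(c(nvox, 1L, 1L), c(1, 1, 1))
  masks <- lapply(masks, function(m) array(m, dim = grid$shape))
  if (is.null(masks$body)) masks$body <- array(TRUE, dim = grid$shape)
  roles <- c(roles, body = "body")[names(masks)]
  dens <- array(1, dim = grid$shape)
  structure(list(grid = grid, density = dens, masks = masks, roles = roles,
                 isocenter_mm = c(0, 0, 0)),
            class = "protonarc_phantom")
}

# Wrap a dense influence matrix (voxels x spots) as a single-scenario dij.
toy_dij <- function(D, field_index = rep(1L, ncol(D)),
                    el_index = seq_len(ncol(D))) {
  spots <- tibble::tibble(id = seq_len(ncol(D)), field_index = field_index,
                          el_index = el_index,
                          range_mm = 100, peak_wet_mm = 100,
                          lat1_mm = seq_len(ncol(D)), lat2_mm = 0)
  beams <- make_beam_set("explicit", angles = sort(unique(field_index)) * 0)
  beams <- beams[seq_along(unique(field_index)), ]
  beams$field_index <- sort(unique(field_index))
  m <- methods::as(Matrix::Matrix(D, sparse = TRUE), "CsparseMatrix")
  colnames(m) <- as.character(spots$id)
  attr(spots, "beams") <- beams
  structure(list(grid = grid_spec(c(nrow(D), 1L, 1L), c(1, 1, 1)),
                 spots = spots, beams = beams,
                 scenarios = build_scenarios(mode = "nominal_only"),
                 matrices = list(m)),
            class = "protonarc_dij")
}

#' Registry of hand-sized optimization fixtures
#'
#' Each fixture is a toy planning problem (<= 10 spots, <= 30 voxels)
#' bundled with the brute-force oracle that recomputes its known solution:
#'
#' * `two_spot_lex` — 2 spots, 3 voxels, two prioritized mean-dose
#'   objectives under target min/max constraints; `oracle(res)` grid-searches
#'   the weight box and returns the lexicographic objective vector.
#' * `one_el_sufficient` — 4 spots in 3 energy layers where exactly one EL
#'   can satisfy the constraints alone; `oracle()` enumerates all EL subsets
#'   and returns the minimal feasible ones.
#' * `infeasible_minmax` — contradictory min/max constraints on one voxel.
#'
#' @param name fixture name.
#' @return list with `dij`, `phantom`, `wishlist`, and an `oracle` closure.
#' @export
#' @examples
#' fx <- toy_lp("two_spot_lex")
#' names(fx)
toy_lp <- function(name) {
  switch(name,
    two_spot_lex = {
      D <- rbind(c(1.0, 1.0),    # voxel 1: target
                 c(0.8, 0.1),    # voxel 2: oar_a
                 c(0.1, 0.7))    # voxel 3: oar_b
      phantom <- toy_phantom(3, list(target = c(TRUE, FALSE, FALSE),
                                     oar_a = c(FALSE, TRUE, FALSE),
                                     oar_b = c(FALSE, FALSE, TRUE)),
                             c(target = "target_high", oar_a = "oar_parallel",
                               oar_b = "oar_parallel"))
      wl <- parse_wishlist(list(
        constraints = data.frame(structure = "target",
                                 metric = c("min_dose", "max_dose"),
                                 bound = c(60, 80), robust = FALSE),
        objectives = data.frame(priority = 1:2,
                                structure = c("oar_a", "oar_b"),
                                metric = "mean_dose", goal = c(1, 1),
                                sufficient = FALSE, robust = FALSE)))
      oracle <- function(delta = 0.03, res = 0.05, wmax = 100) {
        # dense grid search over the weight box, replicating the
        # epsilon-constraint sequence by brute force
        w1 <- seq(0, wmax, by = res)
        w2 <- seq(0, wmax, by = res)
        gw <- expand.grid(w1 = w1, w2 = w2)
        dose1 <- gw$w1 * D[1, 1] + gw$w2 * D[1, 2]
        feas <- dose1 >= 60 - 1e-9 & dose1 <= 80 + 1e-9
        f1 <- gw$w1 * D[2, 1] + gw$w2 * D[2, 2]
        f2 <- gw$w1 * D[3, 1] + gw$w2 * D[3, 2]
        best1 <- min(f1[feas])
        feas2 <- feas & f1 <= best1 * (1 + delta) + 1e-9
        best2 <- min(f2[feas2])
        c(best1, best2)
      }
      list(dij = toy_dij(D), phantom = phantom, wishlist = wl, oracle = oracle)
    },
    one_el_sufficient = {
      D <- rbind(c(0.2, 0.2, 1.0, 0.3),   # voxel 1: target
                 c(0.9, 0.9, 0.05, 0.8))  # voxel 2: oar
      el <- c(1L, 1L, 2L, 3L)
      phantom <- toy_phantom(2, list(target = c(TRUE, FALSE),
                                     oar = c(FALSE, TRUE)),
                             c(target = "target_high", oar = "oar_parallel"))
      wl <- parse_wishlist(list(
        constraints = data.frame(structure = c("target", "oar"),
                                 metric = c("min_dose", "max_dose"),
                                 bound = c(60, 20), robust = FALSE),
        objectives = data.frame(priority = 1L, structure = "oar",
                                metric = "mean_dose", goal = 1,
                                sufficient = FALSE, robust = FALSE)))
      oracle <- function() {
        # enumerate every non-empty EL subset; with one min-dose and one
        # max-dose row of positive coefficients, nonnegative weights can
        # meet {d1 >= 60, d2 <= 20} iff some spot j of the subset has
        # D[1,j]/D[2,j] >= 60/20 (all weight on the best-ratio spot;
        # mixtures only interpolate the per-spot ratios)
        els <- sort(unique(el))
        feasible <- character(0)
        for (k in seq_along(els)) {
          for (sub in utils::combn(els, k, simplify = FALSE)) {
            cols <- which(el %in% sub)
            if (any(D[1, cols] / D[2, cols] >= 60 / 20 - 1e-12))
              feasible <- c(feasible, paste(sub, collapse = "+"))
          }
        }
        minimal <- feasible[!vapply(feasible, function(f) {
          mem <- as.integer(strsplit(f, "\\+")[[1]])
          any(vapply(feasible, function(g) {
            gm <- as.integer(strsplit(g, "\\+")[[1]])
            length(gm) < length(mem) && all(gm %in% mem)
          }, logical(1)))
        }, logical(1))]
        list(feasible = feasible, minimal = minimal)
      }
      list(dij = toy_dij(D, el_index = el), phantom = phantom, wishlist = wl,
           oracle = oracle)
    },
    infeasible_minmax = {
      D <- matrix(c(1.0, 0.5), 1, 2)
      phantom <- toy_phantom(1, list(target = TRUE),
                             c(target = "target_high"))
      wl <- parse_wishlist(list(
        constraints = data.frame(structure = "target",
                                 metric = c("min_dose", "max_dose"),
                                 bound = c(70, 60), robust = FALSE),
        objectives = data.frame(priority = 1L, structure = "target",
                                metric = "mean_dose", goal = 60,
                                sufficient = FALSE, robust = FALSE)))
      list(dij = toy_dij(D), phantom = phantom, wishlist = wl,
           oracle = function() "infeasible")
    },
    stop_protonarc(sprintf("unknown fixture '%s'", name), "protonarc_spec_error")
  )
}

#' Names of the registered fixtures
#' @return character vector.
#' @export
toy_lp_names <- function() c("two_spot_lex", "one_el_sufficient", "infeasible_minmax")

#' Homogeneous water-slab phantom
#'
#' The dose-engine verification bed: a slab of uniform relative stopping
#' power with a box target spanning a given depth interval along the
#' gantry-0 beam direction (entry at the +y face).
#'
#' @param depth_mm slab thickness along the beam (mm).
#' @param target_span depth interval (mm from the entry face) of the box
#'   target.
#' @param spacing_mm voxel spacing (mm).
#' @param density relative stopping power of the slab.
#' @param width_mm lateral slab width (mm).
#' @return a `protonarc_phantom`.
#' @export
slab_phantom <- function(depth_mm = 160, target_span = c(80, 120),
                         spacing_mm = 4, density = 1, width_mm = 64) {
  if (any(target_span <= 0) || diff(target_span) < 0)
    stop_protonarc("target span must be positive and ordered", "protonarc_spec_error")
  nx <- ceiling(width_mm / spacing_mm)
  ny <- ceiling(depth_mm / spacing_mm)
  grid <- grid_spec(c(nx, ny, 1L), rep(spacing_mm, 3))
  centers <- voxel_centers(grid)
  y_entry <- grid$origin_mm[2] + ny * spacing_mm  # beam enters at +y face
  depth <- y_entry - centers[, 2]
  tmask <- depth >= target_span[1] & depth <= target_span[2] &
    abs(centers[, 1]) <= width_mm / 4
  masks <- list(body = array(TRUE, dim = grid$shape),
                target = array(tmask, dim = grid$shape))
  dens <- array(density, dim = grid$shape)
  iso <- colMeans(centers[tmask, , drop = FALSE])
  structure(list(grid = grid, density = dens, masks = masks,
                 roles = c(body = "body", target = "target_high"),
                 isocenter_mm = iso),
            class = "protonarc_phantom")
}
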