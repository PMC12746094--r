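# Beam configurations, candidate spots/energy layers, and the simplified
# analytic pencil-beam dose model.
#
# Beams are parallel-ray (infinite SAD). Gantry angle g (couch 0) gives a
# travel direction d = (sin g, -cos g, 0): at g = 0 the beam enters from +y.
# Couch rotation is applied about the y axis. Lateral axes: l1 = in-plane,
# l2 = cross(d, l1) (z for coplanar beams). Lateral spot coordinates are
# measured from the isocenter (center of mass of the elective target).

#' Construct a beam set for a planning mode
#'
#' Modes: `pat36`/`utopia36` (36 coplanar equiangular fields starting at 0
#' degrees, no range shifter), `cs4` (the four-field clinical class solution,
#' range shifter in all fields), `cs6` (the six-field class solution, range
#' shifter in all fields except gantry 160 and 200), `bao_candidates`
#' (72 coplanar equiangular candidates), `explicit` (caller-supplied angles).
#'
#' @param mode one of `"pat36"`, `"utopia36"`, `"cs4"`, `"cs6"`,
#'   `"bao_candidates"`, `"explicit"`.
#' @param angles for `explicit`: numeric gantry angles, or a 2-column matrix
#'   of (gantry, couch) pairs.
#' @param range_shifter for `explicit`/arc modes: logical, use a range
#'   shifter in every field.
#' @param rs_wet_mm range-shifter water-equivalent thickness (mm).
#' @return tibble with `field_index`, `gantry_deg`, `couch_deg`,
#'   `range_shifter`, `rs_wet_mm`.
#' @export
#' @examples
#' make_beam_set("cs4")$gantry_deg
make_beam_set <- function(mode, angles = NULL, range_shifter = FALSE,
                          rs_wet_mm = 34) {
  known <- c("pat36", "utopia36", "cs4", "cs6", "bao_candidates", "explicit")
  if (!mode %in% known)
    stop_protonarc(sprintf("unknown beam-set mode '%s'", mode), "protonarc_spec_error")
  beams <- switch(mode,
    pat36 = ,
    utopia36 = tibble::tibble(gantry_deg = seq(0, 350, by = 10), couch_deg = 0,
                              range_shifter = range_shifter),
    cs4 = tibble::tibble(gantry_deg = c(150, 60, 300, 210), couch_deg = 0,
                         range_shifter = TRUE),
    cs6 = tibble::tibble(gantry_deg = c(200, 260, 310, 50, 100, 160),
                         couch_deg = c(0, 20, 0, 0, 340, 0),
                         range_shifter = !c(200, 260, 310, 50, 100, 160) %in% c(160, 200)),
    bao_candidates = tibble::tibble(gantry_deg = seq(0, 355, by = 5), couch_deg = 0,
                                    range_shifter = range_shifter),
    explicit = {
      if (is.null(angles))
        stop_protonarc("mode 'explicit' requires angles", "protonarc_spec_error")
      if (is.matrix(angles))
        tibble::tibble(gantry_deg = angles[, 1], couch_deg = angles[, 2],
                       range_shifter = range_shifter)
      else
        tibble::tibble(gantry_deg = as.numeric(angles), couch_deg = 0,
                       range_shifter = range_shifter)
    })
  beams$rs_wet_mm <- rs_wet_mm
  beams$field_index <- seq_len(nrow(beams))
  beams[, c("field_index", "gantry_deg", "couch_deg", "range_shifter", "rs_wet_mm")]
}

# Unit axes of a beam: travel direction d and lateral axes l1, l2.
beam_axes <- function(gantry_deg, couch_deg = 0) {
  g <- gantry_deg * pi / 180
  c_ <- couch_deg * pi / 180
  rz <- function(v) c(cos(g) * v[1] - sin(g) * v[2],
                      sin(g) * v[1] + cos(g) * v[2], v[3])
  ry <- function(v) c(cos(c_) * v[1] + sin(c_) * v[3], v[2],
                      -sin(c_) * v[1] + cos(c_) * v[3])
  d <- ry(rz(c(0, -1, 0)))
  l1 <- ry(rz(c(1, 0, 0)))
  l2 <- c(d[2] * l1[3] - d[3] * l1[2],
          d[3] * l1[1] - d[1] * l1[3],
          d[1] * l1[2] - d[2] * l1[1])
  list(d = d, l1 = l1, l2 = l2)
}

#' Dose-engine model parameters
#'
#' Parameters of the simplified analytic pencil-beam model: a parametric
#' Bragg depth-dose (Gaussian-smeared peak of width `peak_sigma_mm` on a
#' gently rising entrance plateau) and a lateral Gaussian of depth-growing
#' sigma, sigma(z)^2 = sigma0^2 + (k z)^2 (+ sigma_rs^2 with a range
#' shifter).
#'
#' @param sigma0_mm lateral sigma at the surface (mm).
#' @param k dimensionless depth-broadening slope.
#' @param sigma_rs_mm extra lateral sigma (quadrature) from a range shifter.
#' @param peak_sigma_mm Bragg-peak Gaussian width (mm WET).
#' @param plateau entrance-plateau level relative to the peak term.
#' @param buildup fractional plateau rise from surface to peak.
#' @param falloff_tau_mm distal plateau falloff length (mm WET).
#' @param dose_scale_gy_mm2 amplitude so that doses per MU are of order
#'   0.1-1 Gy at the peak.
#' @param step_mm ray-march step for radiological depth (mm).
#' @param sparsity_floor relative floor below which influence entries are
#'   dropped (fraction of the column maximum).
#' @param lateral_cutoff_sigma lateral truncation radius in units of sigma.
#' @return a list of engine parameters.
#' @export
beam_model <- function(sigma0_mm = 3, k = 0.03, sigma_rs_mm = 4,
                       peak_sigma_mm = 3, plateau = 0.3, buildup = 0.3,
                       falloff_tau_mm = 2, dose_scale_gy_mm2 = 60,
                       step_mm = 2, sparsity_floor = 1e-4,
                       lateral_cutoff_sigma = 3.5) {
  as.list(environment())
}

# Parametric Bragg depth-dose at radiological depth z for peak range R (WET mm).
bragg_depth_dose <- function(z, range_mm, model = beam_model()) {
  peak <- exp(-(z - range_mm)^2 / (2 * model$peak_sigma_mm^2))
  plat <- model$plateau * (1 + model$buildup * pmax(z, 0) / range_mm) *
    stats::plogis((range_mm - z) / model$falloff_tau_mm)
  out <- peak + plat
  out[z < 0] <- 0
  out
}

lateral_sigma <- function(z_wet, range_shifter, model = beam_model()) {
  sqrt(model$sigma0_mm^2 + (model$k * z_wet)^2 +
         ifelse(range_shifter, model$sigma_rs_mm^2, 0))
}

# Radiological depth (WET, mm) of every voxel center along direction d,
# under an optional global density scaling. Midpoint ray-march with nearest
# -neighbour density sampling; density outside the grid is 0 (air).
wet_map <- function(phantom, d, step_mm = 2, range_scale = 1) {
  g <- phantom$grid
  centers <- voxel_centers(g)
  diam <- sqrt(sum((g$shape * g$spacing_mm)^2)) + 2 * step_mm
  n <- ceiling(diam / step_mm)
  dens <- as.vector(phantom$density) * range_scale
  w <- numeric(nrow(centers))
  for (i in seq_len(n)) {
    t_i <- (i - 0.5) * step_mm
    pos <- centers - matrix(t_i * d, nrow(centers), 3, byrow = TRUE)
    idx <- world_to_voxel(g, pos)
    ok <- !is.na(idx)
    w[ok] <- w[ok] + dens[idx[ok]] * step_mm
  }
  w
}

# WET profile along a single ray through axis point q (world coords, on the
# isocenter plane), sampled from upstream entry towards the exit.
ray_march <- function(phantom, q, d, step_mm = 1, range_scale = 1) {
  g <- phantom$grid
  diam <- sqrt(sum((g$shape * g$spacing_mm)^2)) + 2 * step_mm
  t <- seq(-diam, diam, by = step_mm)
  pos <- cbind(q[1] + t * d[1], q[2] + t * d[2], q[3] + t * d[3])
  idx <- world_to_voxel(g, pos)
  dens <- ifelse(is.na(idx), 0, as.vector(phantom$density)[idx]) * range_scale
  list(t = t, pos = pos, idx = idx, wet = cumsum(dens) * step_mm)
}

#' Central-axis Bragg-peak depth along a ray
#'
#' Marches the central axis of a pencil beam through the phantom and returns
#' the geometric depth (mm past the isocenter-plane entry point of the
#' medium) at which the analytic depth-dose is maximal. With a range
#' shifter, the in-patient peak sits at `range_mm - rs_wet_mm` of
#' water-equivalent depth, i.e. it is pulled back by the shifter WET.
#'
#' @param phantom a `protonarc_phantom`.
#' @param gantry_deg,couch_deg beam angles (degrees).
#' @param lat_mm lateral spot position (length 2, mm).
#' @param range_mm machine-side water-equivalent range of the spot (mm).
#' @param range_shifter logical.
#' @param rs_wet_mm shifter water-equivalent thickness (mm).
#' @param model [beam_model()] parameters.
#' @param step_mm march step (mm).
#' @return depth of maximum dose, in mm past the first non-zero-density
#'   sample of the ray.
#' @export
bragg_peak_depth <- function(phantom, gantry_deg = 0, couch_deg = 0,
                             lat_mm = c(0, 0), range_mm,
                             range_shifter = FALSE, rs_wet_mm = 34,
                             model = beam_model(), step_mm = 0.25) {
  ax <- beam_axes(gantry_deg, couch_deg)
  q <- phantom$isocenter_mm + lat_mm[1] * ax$l1 + lat_mm[2] * ax$l2
  rm_ <- ray_march(phantom, q, ax$d, step_mm = step_mm)
  r_pat <- range_mm - if (range_shifter) rs_wet_mm else 0
  if (r_pat <= 0)
    stop_protonarc("in-patient range is non-positive under this shifter",
                   "protonarc_spec_error")
  dd <- bragg_depth_dose(rm_$wet, r_pat, model)
  entry <- which(rm_$wet > 0)[1]
  (which.max(dd) - entry) * step_mm
}

#' Generate candidate spots for one beam
#'
#' Lays a lateral spot grid over the beam's-eye-view projection of the
#' union target expanded by `margin_mm`, and per lateral position places
#' energy layers at `el_spacing_wet_mm` steps spanning the proximal-distal
#' radiological depth of the target voxels assigned to that position
#' (expanded by `margin_mm` of WET). With a range shifter the machine range
#' is the in-patient peak WET plus the shifter WET.
#'
#' @param phantom a `protonarc_phantom`.
#' @param beam one row of a [make_beam_set()] tibble.
#' @param lateral_spacing_mm lateral spot grid spacing (mm).
#' @param el_spacing_wet_mm energy-layer spacing (mm WET).
#' @param margin_mm lateral and radiological margin around the target (mm).
#' @param model [beam_model()] parameters.
#' @return tibble of spots: `id` (NA until pooled), `field_index`,
#'   `el_index`, `range_mm` (machine WET range), `peak_wet_mm` (in-patient
#'   Bragg-peak WET), `lat1_mm`, `lat2_mm`.
#' @export
generate_candidate_spots <- function(phantom, beam, lateral_spacing_mm = 6,
                                     el_spacing_wet_mm = 6, margin_mm = 5,
                                     model = beam_model()) {
  if (lateral_spacing_mm <= 0 || el_spacing_wet_mm <= 0)
    stop_protonarc("spot spacings must be positive", "protonarc_spec_error")
  ax <- beam_axes(beam$gantry_deg, beam$couch_deg)
  tv <- which(as.vector(target_union(phantom)))
  if (!length(tv)) {
    warning(sprintf("field %d: empty target projection, no spots", beam$field_index))
    return(empty_spots())
  }
  centers <- voxel_centers(phantom$grid)
  pc <- sweep(centers[tv, , drop = FALSE], 2, phantom$isocenter_mm)
  e1 <- as.vector(pc %*% ax$l1)
  e2 <- as.vector(pc %*% ax$l2)
  w <- wet_map(phantom, ax$d, step_mm = model$step_mm)[tv]
  # spot lattice anchored at the isocenter (multiples of the spacing):
  # keeps quasi-2D slabs covered by an on-axis spot row
  lat_grid <- function(vals) {
    kmin <- ceiling((min(vals) - margin_mm) / lateral_spacing_mm - 1e-9)
    kmax <- floor((max(vals) + margin_mm) / lateral_spacing_mm + 1e-9)
    if (kmax < kmin) return(round(mean(range(vals)) / lateral_spacing_mm) *
                              lateral_spacing_mm)
    (kmin:kmax) * lateral_spacing_mm
  }
  g1 <- lat_grid(e1)
  g2 <- lat_grid(e2)
  a <- vapply(e1, function(v) which.min(abs(g1 - v)), integer(1))
  b <- vapply(e2, function(v) which.min(abs(g2 - v)), integer(1))
  rows <- list()
  for (key in unique(paste(a, b))) {
    sel <- paste(a, b) == key
    ai <- a[sel][1]; bi <- b[sel][1]
    wlo <- max(el_spacing_wet_mm / 2, min(w[sel]) - margin_mm)
    whi <- max(w[sel]) + margin_mm
    els <- seq(wlo, whi + 1e-9, by = el_spacing_wet_mm)
    rows[[key]] <- tibble::tibble(peak_wet_mm = els, lat1_mm = g1[ai], lat2_mm = g2[bi])
  }
  sp <- dplyr::bind_rows(rows)
  sp$range_mm <- sp$peak_wet_mm + if (beam$range_shifter) beam$rs_wet_mm else 0
  sp$field_index <- beam$field_index
  sp$el_index <- match(sp$range_mm, sort(unique(sp$range_mm)))
  sp$id <- NA_integer_
  sp <- sp[order(sp$el_index, sp$lat1_mm, sp$lat2_mm), ]
  sp[, c("id", "field_index", "el_index", "range_mm", "peak_wet_mm",
         "lat1_mm", "lat2_mm")]
}

empty_spots <- function() {
  tibble::tibble(id = integer(), field_index = integer(), el_index = integer(),
                 range_mm = numeric(), peak_wet_mm = numeric(),
                 lat1_mm = numeric(), lat2_mm = numeric())
}

#' Candidate spots for a whole beam set
#'
#' Pools [generate_candidate_spots()] over all fields, assigns global spot
#' ids, and (optionally) removes spots whose entrance ray traverses a
#' blocking structure.
#'
#' @param phantom a `protonarc_phantom`.
#' @param beams a [make_beam_set()] tibble.
#' @param block logical; apply [block_spots()] with every `blocking`-role
#'   structure of the phantom.
#' @inheritParams generate_candidate_spots
#' @return spot tibble with the `beams` tibble attached as attribute
#'   `"beams"`.
#' @export
candidate_spots <- function(phantom, beams, lateral_spacing_mm = 6,
                            el_spacing_wet_mm = 6, margin_mm = 5,
                            model = beam_model(), block = TRUE) {
  sp <- dplyr::bind_rows(lapply(seq_len(nrow(beams)), function(i)
    generate_candidate_spots(phantom, beams[i, ], lateral_spacing_mm,
                             el_spacing_wet_mm, margin_mm, model)))
  sp$id <- seq_len(nrow(sp))
  attr(sp, "beams") <- beams
  blocking <- structures_by_role(phantom, "blocking")
  if (block && length(blocking))
    sp <- block_spots(sp, phantom, blocking, beams = beams, model = model)
  sp
}

#' Remove spots whose entrance ray crosses a blocking structure
#'
#' A spot is removed when any sample of its central ray, from the upstream
#' grid entry to the Bragg-peak position, lies inside one of the named
#' blocking masks. Order and ids of the surviving spots are unchanged.
#'
#' @param spots spot tibble (from [candidate_spots()]).
#' @param phantom a `protonarc_phantom`.
#' @param blocking_names names of blocking masks in `phantom$masks`.
#' @param beams beam tibble; defaults to the `"beams"` attribute of `spots`.
#' @param model [beam_model()] parameters (march step).
#' @return the filtered spot tibble (attributes preserved).
#' @export
block_spots <- function(spots, phantom, blocking_names,
                        beams = attr(spots, "beams"), model = beam_model()) {
  unknown <- setdiff(blocking_names, names(phantom$masks))
  if (length(unknown))
    stop_protonarc(sprintf("unknown blocking structure(s): %s",
                           paste(unknown, collapse = ", ")),
                   "protonarc_spec_error")
  if (!nrow(spots)) return(spots)
  bmask <- as.vector(Reduce(`|`, phantom$masks[blocking_names]))
  keep <- logical(nrow(spots))
  for (f in unique(spots$field_index)) {
    brow <- beams[beams$field_index == f, ]
    ax <- beam_axes(brow$gantry_deg, brow$couch_deg)
    for (i in which(spots$field_index == f)) {
      q <- phantom$isocenter_mm + spots$lat1_mm[i] * ax$l1 + spots$lat2_mm[i] * ax$l2
      rm_ <- ray_march(phantom, q, ax$d, step_mm = model$step_mm)
      upto <- which(rm_$wet >= spots$peak_wet_mm[i])[1]
      if (is.na(upto)) upto <- length(rm_$t)
      seg <- rm_$idx[seq_len(upto)]
      seg <- seg[!is.na(seg)]
      keep[i] <- !any(bmask[seg])
    }
  }
  out <- spots[keep, ]
  attr(out, "beams") <- beams
  out
}

#' Compute per-scenario dose-influence matrices
#'
#' For every scenario, builds the sparse (voxel x spot) matrix of dose per
#' MU under the simplified pencil-beam model: dose at voxel v equals
#' `dose_scale * B(W_s(v); R) * G(r; sigma(W_s(v))) / (2 pi sigma^2)`, where
#' `W_s` is the nominal per-voxel radiological depth map scaled by the
#' scenario's `range_scale`, `B` the analytic Bragg depth-dose with
#' in-patient peak at `R = range_mm - rs_wet_mm` (shifter upstream), and `r`
#' the lateral distance to the spot axis shifted by the scenario's setup
#' error (patient displacement; the dose pattern moves opposite in the
#' patient frame). Entries below `sparsity_floor` times the column maximum
#' are dropped.
#'
#' @param phantom a `protonarc_phantom`.
#' @param spots spot tibble from [candidate_spots()].
#' @param scenarios scenario tibble from [build_scenarios()].
#' @param beams beam tibble; defaults to the `"beams"` attribute of `spots`.
#' @param model [beam_model()] parameters.
#' @return a `protonarc_dij`: list with `grid`, `spots`, `beams`,
#'   `scenarios`, and `matrices` (one `dgCMatrix` per scenario, columns
#'   named by spot id).
#' @export
compute_dij <- function(phantom, spots, scenarios = build_scenarios(mode = "nominal_only"),
                        beams = attr(spots, "beams"), model = beam_model()) {
  if (!nrow(spots))
    stop_protonarc("no candidate spots", "protonarc_spec_error")
  g <- phantom$grid
  nvox <- prod(g$shape)
  centers <- voxel_centers(g)
  nscen <- nrow(scenarios)
  trip <- lapply(seq_len(nscen), function(s) list(i = list(), j = list(), x = list()))
  for (f in unique(spots$field_index)) {
    brow <- beams[beams$field_index == f, ]
    ax <- beam_axes(brow$gantry_deg, brow$couch_deg)
    w0 <- wet_map(phantom, ax$d, step_mm = model$step_mm)
    pc <- sweep(centers, 2, phantom$isocenter_mm)
    e1 <- as.vector(pc %*% ax$l1)
    e2 <- as.vector(pc %*% ax$l2)
    rs_wet <- if (brow$range_shifter) brow$rs_wet_mm else 0
    srows <- which(spots$field_index == f)
    for (s in seq_len(nscen)) {
      sc <- scenarios[s, ]
      ws <- w0 * sc$range_scale
      shift <- c(sc$sx_mm, sc$sy_mm, sc$sz_mm)
      ds1 <- sum(shift * ax$l1)
      ds2 <- sum(shift * ax$l2)
      for (i in srows) {
        r_pat <- spots$range_mm[i] - rs_wet
        a <- spots$lat1_mm[i] - ds1
        b <- spots$lat2_mm[i] - ds2
        sig_max <- lateral_sigma(r_pat + 3 * model$peak_sigma_mm,
                                 brow$range_shifter, model)
        rcut <- model$lateral_cutoff_sigma * sig_max
        cand <- which(abs(e1 - a) <= rcut & abs(e2 - b) <= rcut &
                        ws <= r_pat + 5 * model$peak_sigma_mm & ws > 0)
        if (!length(cand)) next
        sig <- lateral_sigma(ws[cand], brow$range_shifter, model)
        r2 <- (e1[cand] - a)^2 + (e2[cand] - b)^2
        dose <- model$dose_scale_gy_mm2 *
          bragg_depth_dose(ws[cand], r_pat, model) *
          exp(-r2 / (2 * sig^2)) / (2 * pi * sig^2)
        keep <- dose >= model$sparsity_floor * max(dose)
        if (!any(keep)) next
        trip[[s]]$i[[length(trip[[s]]$i) + 1L]] <- cand[keep]
        trip[[s]]$j[[length(trip[[s]]$j) + 1L]] <-
          rep.int(match(i, seq_len(nrow(spots))), sum(keep))
        trip[[s]]$x[[length(trip[[s]]$x) + 1L]] <- dose[keep]
      }
    }
  }
  mats <- lapply(seq_len(nscen), function(s) {
    m <- Matrix::sparseMatrix(
      i = unlist(trip[[s]]$i), j = unlist(trip[[s]]$j),
      x = unlist(trip[[s]]$x), dims = c(nvox, nrow(spots)))
    colnames(m) <- as.character(spots$id)
    m
  })
  structure(list(grid = g, spots = spots, beams = beams,
                 scenarios = scenarios, matrices = mats),
            class = "protonarc_dij")
}

#' @exportS3Method base::print
print.protonarc_dij <- function(x, ...) {
  cat(sprintf("<protonarc_dij> %d spots, %d fields, %d scenarios, %d voxels\n",
              nrow(x$spots), nrow(x$beams), nrow(x$scenarios),
              prod(x$grid$shape)))
  invisible(x)
}

#' Restrict a dose-influence set to a spot support
#'
#' @param dij a `protonarc_dij`.
#' @param ids spot ids to keep.
#' @return the restricted `protonarc_dij` (spot order preserved).
#' @export
dij_subset <- function(dij, ids) {
  keep <- dij$spots$id %in% ids
  dij$spots <- dij$spots[keep, ]
  dij$matrices <- lapply(dij$matrices, function(m) m[, keep, drop = FALSE])
  dij
}

# Dose raster (vector over voxels) for weights w (aligned to dij$spots).
dose_vector <- function(dij, w, scenario = 1L) {
  as.vector(dij$matrices[[scenario]] %*% w)
}

#' Serialize / load a dose-influence set
#'
#' Writes `spots.json`, `beams.json`, `scenarios.json`, `grid.json` and one
#' MatrixMarket file per scenario under `dir`.
#'
#' @param dij a `protonarc_dij`.
#' @param dir directory.
#' @export
write_dij <- function(dij, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(dij$spots, file.path(dir, "spots.json"), digits = NA)
  jsonlite::write_json(dij$beams, file.path(dir, "beams.json"), digits = NA)
  jsonlite::write_json(dij$scenarios, file.path(dir, "scenarios.json"), digits = NA)
  jsonlite::write_json(list(shape = dij$grid$shape, spacing_mm = dij$grid$spacing_mm,
                            origin_mm = dij$grid$origin_mm),
                       file.path(dir, "grid.json"), digits = NA)
  for (s in seq_along(dij$matrices))
    Matrix::writeMM(dij$matrices[[s]], file.path(dir, sprintf("scenario_%02d.mtx", s)))
  invisible(dir)
}

#' @rdname write_dij
#' @export
read_dij <- function(dir) {
  gj <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- grid_spec(gj$shape, gj$spacing_mm, gj$origin_mm)
  spots <- tibble::as_tibble(jsonlite::read_json(file.path(dir, "spots.json"),
                                                 simplifyVector = TRUE))
  beams <- tibble::as_tibble(jsonlite::read_json(file.path(dir, "beams.json"),
                                                 simplifyVector = TRUE))
  scen <- tibble::as_tibble(jsonlite::read_json(file.path(dir, "scenarios.json"),
                                                simplifyVector = TRUE))
  mats <- lapply(seq_len(nrow(scen)), function(s) {
    m <- methods::as(Matrix::readMM(file.path(dir, sprintf("scenario_%02d.mtx", s))),
                     "CsparseMatrix")
    colnames(m) <- as.character(spots$id)
    m
  })
  attr(spots, "beams") <- beams
  structure(list(grid = grid, spots = spots, beams = beams, scenarios = scen,
                 matrices = mats), class = "protonarc_dij")
}
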