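# Synthetic oropharynx-like phantoms: density grid + structure masks.
#
# Coordinate convention: 0-based voxel indices; world position of voxel
# (i,j,k) is origin + (index + 0.5) * spacing. All lengths in mm.

#' Define a voxel grid
#'
#' @param shape integer triple (nx, ny, nz), all >= 1.
#' @param spacing_mm positive voxel spacing triple (mm).
#' @param origin_mm world coordinate of the grid corner (mm); defaults to a
#'   grid centred on the world origin.
#' @return a `protonarc_grid` list with `shape`, `spacing_mm`, `origin_mm`.
#' @export
#' @examples
#' g <- grid_spec(c(10, 10, 1), c(3, 3, 3))
#' voxel_volume_ml(g) * prod(g$shape)  # total grid volume in mL
grid_spec <- function(shape, spacing_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_protonarc("grid shape must be 3 integers >= 1", "protonarc_bounds_error")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_protonarc("grid spacing must be 3 positive numbers", "protonarc_bounds_error")
  if (is.null(origin_mm)) origin_mm <- -shape * spacing_mm / 2
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "protonarc_grid")
}

#' @rdname grid_spec
#' @param grid a `protonarc_grid`.
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing_mm) / 1000

#' World coordinates of all voxel centers
#'
#' @param grid a `protonarc_grid`.
#' @return numeric matrix (n_voxels x 3), x-fastest ordering (matching R's
#'   array linearization).
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape
  ax <- lapply(1:3, function(d)
    grid$origin_mm[d] + (seq_len(s[d]) - 0.5) * grid$spacing_mm[d])
  cbind(rep(ax[[1]], times = s[2] * s[3]),
        rep(rep(ax[[2]], each = s[1]), times = s[3]),
        rep(ax[[3]], each = s[1] * s[2]))
}

# Map world points (n x 3) to linear voxel indices; NA outside the grid.
world_to_voxel <- function(grid, pts) {
  s <- grid$shape
  ijk <- sweep(sweep(pts, 2, grid$origin_mm), 2, grid$spacing_mm, "/")
  ijk <- floor(ijk)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < s[1] &
        ijk[, 2] >= 0 & ijk[, 2] < s[2] &
        ijk[, 3] >= 0 & ijk[, 3] < s[3]
  idx <- rep(NA_integer_, nrow(pts))
  idx[ok] <- as.integer(1 + ijk[ok, 1] + s[1] * (ijk[ok, 2] + s[2] * ijk[ok, 3]))
  idx
}

# --- geometric primitives (voxel-center-inside tests) -----------------------

inside_structure <- function(centers, st) {
  p <- sweep(centers, 2, st$center_mm)
  switch(st$type,
    ellipsoid = rowSums(sweep(p, 2, st$semiaxes_mm, "/")^2) <= 1,
    sphere = rowSums(p^2) <= st$radius_mm^2,
    cylinder_z = (p[, 1]^2 + p[, 2]^2 <= st$radius_mm^2) &
      abs(p[, 3]) <= (st$half_length_mm %||% Inf),
    box = abs(p[, 1]) <= st$half_mm[1] & abs(p[, 2]) <= st$half_mm[2] &
      abs(p[, 3]) <= st$half_mm[3],
    shell = {
      a <- rowSums(sweep(p, 2, st$outer_semiaxes_mm, "/")^2) <= 1
      b <- rowSums(sweep(p, 2, st$inner_semiaxes_mm, "/")^2) <= 1
      a & !b
    },
    stop_protonarc(sprintf("unknown structure type '%s'", st$type),
                   "protonarc_spec_error")
  )
}

structure_extent <- function(st) {
  half <- switch(st$type,
    ellipsoid = st$semiaxes_mm,
    sphere = rep(st$radius_mm, 3),
    cylinder_z = c(st$radius_mm, st$radius_mm, st$half_length_mm %||% Inf),
    box = st$half_mm,
    shell = st$outer_semiaxes_mm)
  rbind(st$center_mm - half, st$center_mm + half)
}

#' Default parametric phantom specification
#'
#' A quasi-2D (single axial slice) stand-in for an oropharyngeal planning
#' case: an elliptical body, a high-dose target (CTV70-like sphere) nested
#' in an elective target (CTV54.25-like ellipsoid), two lateral parotid-like
#' ellipsoids, a posterior midline cord-like cylinder, a
#' pharyngeal-constrictor-like shell, and two shoulder-like blocking slabs.
#'
#' @param nz number of axial slices (1 = quasi-2D, the desk-scale default).
#' @param spacing_mm isotropic voxel spacing (mm).
#' @return a phantom spec list consumed by [generate_phantom()].
#' @export
default_phantom_spec <- function(nz = 1L, spacing_mm = 4) {
  sp <- rep(spacing_mm, 3)
  nxy <- as.integer(ceiling(176 / spacing_mm))  # fixed 176 mm in-plane extent
  list(
    grid = grid_spec(c(nxy, nxy, as.integer(nz)), sp),
    body = list(type = "ellipsoid", center_mm = c(0, 0, 0),
                semiaxes_mm = c(80, 70, 1e6)),
    structures = list(
      ctv70 = list(type = "sphere", center_mm = c(12, 8, 0), radius_mm = 15,
                   role = "target_high"),
      ctv5425 = list(type = "ellipsoid", center_mm = c(0, 6, 0),
                     semiaxes_mm = c(34, 24, 1e6), role = "target_elective"),
      parotid_l = list(type = "ellipsoid", center_mm = c(52, 10, 0),
                       semiaxes_mm = c(11, 13, 1e6), role = "oar_parallel"),
      parotid_r = list(type = "ellipsoid", center_mm = c(-52, 10, 0),
                       semiaxes_mm = c(11, 13, 1e6), role = "oar_parallel"),
      constrictor = list(type = "shell", center_mm = c(0, -24, 0),
                         outer_semiaxes_mm = c(16, 9, 1e6),
                         inner_semiaxes_mm = c(10, 4, 1e6), role = "oar_parallel"),
      cord = list(type = "cylinder_z", center_mm = c(0, -48, 0),
                  radius_mm = 5.5, role = "oar_serial"),
      shoulder_l = list(type = "box", center_mm = c(54, -34, 0),
                        half_mm = c(7, 8, 1e6), role = "blocking"),
      shoulder_r = list(type = "box", center_mm = c(-54, -34, 0),
                        half_mm = c(7, 8, 1e6), role = "blocking")
    ),
    density = list(body = 1.0, air = 0.0, blocking = 1.0),
    jitter = list(center_sd_mm = 2, radius_rel_sd = 0.05)
  )
}

#' Generate a synthetic phantom
#'
#' Rasterizes the parametric spec by a voxel-center-inside test. The seed
#' controls a small anatomical perturbation (structure centers and sizes)
#' so that seeded populations of phantoms can stand in for a patient cohort;
#' the same (spec, seed) pair always yields a bitwise-identical phantom.
#'
#' @param spec phantom spec, see [default_phantom_spec()].
#' @param seed integer seed for the anatomical jitter.
#' @param jitter logical; apply the seeded perturbation (default TRUE when
#'   `spec$jitter` is present).
#' @return a `protonarc_phantom`: list with `grid`, `density` (3-D array of
#'   relative stopping power), `masks` (named logical arrays), `roles`
#'   (named character vector), `isocenter_mm`.
#' @export
#' @examples
#' ph <- generate_phantom(default_phantom_spec(), seed = 1)
#' names(ph$masks)
generate_phantom <- function(spec, seed = 1L, jitter = !is.null(spec$jitter)) {
  grid <- spec$grid
  structures <- spec$structures
  if (jitter) {
    structures <- with_seed(seed, lapply(structures, function(st) {
      st$center_mm <- st$center_mm +
        c(stats::rnorm(2, 0, spec$jitter$center_sd_mm), 0)
      f <- exp(stats::rnorm(1, 0, spec$jitter$radius_rel_sd))
      for (fld in c("radius_mm", "semiaxes_mm", "outer_semiaxes_mm",
                    "inner_semiaxes_mm", "half_mm"))
        if (!is.null(st[[fld]])) st[[fld]] <- st[[fld]] * f
      st
    }))
  }
  centers <- voxel_centers(grid)
  lo <- grid$origin_mm
  hi <- grid$origin_mm + grid$shape * grid$spacing_mm
  body_in <- inside_structure(centers, spec$body)
  if (!any(body_in))
    stop_protonarc("structure 'body' has zero volume on this grid",
                   "protonarc_bounds_error")
  masks <- list(body = array(body_in, dim = grid$shape))
  roles <- c(body = "body")
  for (nm in names(structures)) {
    st <- structures[[nm]]
    ext <- structure_extent(st)
    # bounds are enforced in-plane only for collapsed (single-voxel) axes:
    # quasi-2D slabs are cross-sections of 3-D structures
    fin <- is.finite(ext[1, ]) & is.finite(ext[2, ]) & grid$shape > 1L
    if (any(ext[1, fin] < lo[fin] - 1e-9) || any(ext[2, fin] > hi[fin] + 1e-9))
      stop_protonarc(sprintf("structure '%s' exceeds the grid bounds", nm),
                     "protonarc_bounds_error")
    m <- inside_structure(centers, st) & body_in  # body is a superset by design
    masks[[nm]] <- array(m, dim = grid$shape)
    roles[[nm]] <- st$role
  }
  oars <- names(roles)[roles %in% c("oar_serial", "oar_parallel")]
  th <- names(roles)[roles == "target_high"]
  for (o in oars) for (t in th)
    if (any(masks[[o]] & masks[[t]]))
      warning(sprintf("target '%s' overlaps OAR '%s' (kept, clinically real)", t, o))
  dens <- array(0, dim = grid$shape)
  dens[masks$body] <- spec$density$body %||% 1
  for (nm in names(structures)) {
    dv <- spec$density[[roles[[nm]]]]
    if (!is.null(dv) && roles[[nm]] != "body") dens[masks[[nm]]] <- dv
  }
  elect <- names(roles)[roles == "target_elective"]
  iso_mask <- if (length(elect)) masks[[elect[1]]] else masks[[th[1]]]
  isocenter <- colMeans(centers[as.vector(iso_mask), , drop = FALSE])
  structure(list(grid = grid, density = dens, masks = masks, roles = roles,
                 isocenter_mm = isocenter),
            class = "protonarc_phantom")
}

#' @exportS3Method base::print
print.protonarc_phantom <- function(x, ...) {
  cat(sprintf("<protonarc_phantom> %s voxels @ %s mm\n",
              paste(x$grid$shape, collapse = "x"),
              paste(x$grid$spacing_mm, collapse = "x")))
  vols <- vapply(x$masks, function(m) sum(m) * voxel_volume_ml(x$grid), numeric(1))
  for (nm in names(vols))
    cat(sprintf("  %-12s %-15s %7.1f mL\n", nm, x$roles[[nm]], vols[[nm]]))
  invisible(x)
}

structures_by_role <- function(phantom, role) {
  names(phantom$roles)[phantom$roles %in% role]
}

# Union mask over all target structures.
target_union <- function(phantom) {
  nms <- structures_by_role(phantom, c("target_high", "target_elective"))
  Reduce(`|`, phantom$masks[nms])
}

#' Write / read a phantom as a directory of NRRD rasters
#'
#' The density and each mask are stored as one NRRD file each (shared grid
#' metadata); roles and the isocenter go to `phantom.json`. `read_phantom`
#' round-trips `write_phantom` exactly.
#'
#' @param phantom a `protonarc_phantom`.
#' @param dir directory to write to / read from.
#' @return `read_phantom` returns the phantom; `write_phantom` returns `dir`
#'   invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- phantom$grid
  write_nrrd(phantom$density, file.path(dir, "density.nrrd"),
             g$spacing_mm, g$origin_mm, type = "double")
  for (nm in names(phantom$masks))
    write_nrrd(phantom$masks[[nm]], file.path(dir, paste0("mask_", nm, ".nrrd")),
               g$spacing_mm, g$origin_mm, type = "uchar")
  jsonlite::write_json(
    list(roles = as.list(phantom$roles),
         isocenter_mm = phantom$isocenter_mm,
         masks = names(phantom$masks)),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"), simplifyVector = TRUE)
  dn <- read_nrrd(file.path(dir, "density.nrrd"))
  grid <- grid_spec(dim(dn$data), dn$spacing_mm, dn$origin_mm)
  masks <- list()
  for (nm in meta$masks) {
    m <- read_nrrd(file.path(dir, paste0("mask_", nm, ".nrrd")))
    if (!identical(dim(m$data), dim(dn$data)) ||
        !isTRUE(all.equal(m$spacing_mm, dn$spacing_mm)))
      stop_protonarc(sprintf("grid of mask '%s' does not match the density grid", nm),
                     "protonarc_format_error")
    masks[[nm]] <- array(m$data != 0, dim = dim(m$data))
  }
  roles <- unlist(meta$roles)
  structure(list(grid = grid, density = dn$data, masks = masks, roles = roles,
                 isocenter_mm = as.numeric(meta$isocenter_mm)),
            class = "protonarc_phantom")
}
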