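test_that("class-solution beam sets carry the clinical angles and shifter rules", {
  b4 <- make_beam_set("cs4")
  expect_equal(b4$gantry_deg, c(150, 60, 300, 210))
  expect_true(all(b4$couch_deg == 0))
  expect_true(all(b4$range_shifter))
  expect_true(all(b4$rs_wet_mm == 34))
  b6 <- make_beam_set("cs6")
  expect_equal(b6$gantry_deg, c(200, 260, 310, 50, 100, 160))
  expect_equal(b6$couch_deg, c(0, 20, 0, 0, 340, 0))
  expect_identical(b6$gantry_deg[!b6$range_shifter], c(200, 160))
})

test_that("arc and candidate beam sets are exactly equiangular", {
  p <- make_beam_set("pat36")
  expect_identical(p$gantry_deg, seq(0, 350, by = 10))
  expect_true(all(!p$range_shifter))
  cand <- make_beam_set("bao_candidates")
  expect_identical(nrow(cand), 72L)
  expect_true(all(diff(cand$gantry_deg) == 360 / 72))
  expect_error(make_beam_set("nope"), class = "protonarc_spec_error")
  expect_error(make_beam_set("explicit"), class = "protonarc_spec_error")
})

test_that("energy layers on a water slab match the ray-march depth oracle", {
  ph <- slab_phantom(depth_mm = 160, target_span = c(80, 120), spacing_mm = 4)
  beam <- make_beam_set("explicit", angles = 0)[1, ]
  sp <- generate_candidate_spots(ph, beam, lateral_spacing_mm = 5,
                                 el_spacing_wet_mm = 5, margin_mm = 0)
  central <- sp[abs(sp$lat1_mm) < 2.5 & abs(sp$lat2_mm) < 2.5, ]
  # oracle: WET of a depth-d voxel center in unit-density water equals d;
  # target voxel centers on the central ray span [82, 118]
  centers <- voxel_centers(ph$grid)
  tv <- which(as.vector(ph$masks$target))
  on_ray <- tv[abs(centers[tv, 1] - central$lat1_mm[1]) <= 2.5]
  depth <- (ph$grid$origin_mm[2] + ph$grid$shape[2] * 4) - centers[on_ray, 2]
  span <- range(oracle_slab_wet(depth, 1))
  expect_equal(sort(central$peak_wet_mm),
               seq(span[1], span[2] + 1e-9, by = 5), tolerance = 0.15)
  # margin 0 and a (near) point target still yields at least one EL
  php <- slab_phantom(target_span = c(100, 104), spacing_mm = 4)
  spp <- generate_candidate_spots(php, beam, 5, 5, margin_mm = 0)
  expect_gte(nrow(spp), 1)
})

test_that("opposed beams on a symmetric phantom give mirror-image spot sets", {
  ph <- slab_phantom(depth_mm = 160, target_span = c(60, 100), spacing_mm = 4)
  # recentre the target so the phantom is symmetric under y -> -y
  ph2 <- slab_phantom(depth_mm = 160, target_span = c(60, 100), spacing_mm = 4)
  b0 <- make_beam_set("explicit", angles = 0)[1, ]
  b180 <- make_beam_set("explicit", angles = 180)[1, ]
  s0 <- generate_candidate_spots(ph, b0, 5, 5, 0)
  s180 <- generate_candidate_spots(ph2, b180, 5, 5, 0)
  # the 0-degree spots at depth d correspond to 180-degree spots at
  # (slab depth) - d measured from the other face; lateral axes mirror
  expect_identical(nrow(s0), nrow(s180))
  expect_equal(sort(unique(s0$lat1_mm)), sort(-unique(s180$lat1_mm)))
})

test_that("spot blocking is a filter, idempotent, and matches the ray oracle", {
  ph <- generate_phantom(default_phantom_spec(), seed = 5)
  beams <- make_beam_set("cs4")
  sp <- candidate_spots(ph, beams, 8, 8, 5, block = FALSE)
  blocked <- block_spots(sp, ph, c("shoulder_l", "shoulder_r"), beams = beams)
  expect_true(all(blocked$id %in% sp$id))
  expect_identical(blocked$id, sp$id[sp$id %in% blocked$id])  # order kept
  again <- block_spots(blocked, ph, c("shoulder_l", "shoulder_r"), beams = beams)
  expect_identical(again$id, blocked$id)
  expect_error(block_spots(sp, ph, "nope", beams = beams),
               class = "protonarc_spec_error")
  # independent dense ray-trace oracle on a subsample
  mask <- ph$masks$shoulder_l | ph$masks$shoulder_r
  idx <- seq(1, nrow(sp), by = 7)
  for (i in idx) {
    beam <- beams[beams$field_index == sp$field_index[i], ]
    expect_identical(!sp$id[i] %in% blocked$id,
                     oracle_spot_blocked(ph, sp[i, ], beam, mask),
                     info = sprintf("spot %d", sp$id[i]))
  }
  # a slab mask across the +y entrance fully occludes the 0-degree field
  # (entering from +y) and leaves the opposed field untouched
  beams2 <- make_beam_set("explicit", angles = c(0, 180))
  sp2 <- candidate_spots(ph, beams2, 8, 8, 5, block = FALSE)
  ph_all <- ph
  ph_all$masks$wall <- ph$masks$body & array(
    voxel_centers(ph$grid)[, 2] > 48, dim = ph$grid$shape)
  w <- block_spots(sp2, ph_all, "wall", beams = beams2)
  expect_identical(sum(w$field_index == 1L), 0L)
  expect_identical(w$id[w$field_index == 2L], sp2$id[sp2$field_index == 2L])
  # no blocking mask on any ray: identity
  ph_none <- ph
  ph_none$masks$empty <- array(FALSE, dim = ph$grid$shape)
  expect_identical(block_spots(sp, ph_none, "empty", beams = beams)$id, sp$id)
})

test_that("dose columns are nonnegative, linear, and peak at the spot range", {
  ph <- slab_phantom()
  beams <- make_beam_set("explicit", angles = 0)
  sp <- tibble::tibble(id = 1L, field_index = 1L, el_index = 1L,
                       range_mm = 100, peak_wet_mm = 100, lat1_mm = 0, lat2_mm = 0)
  attr(sp, "beams") <- beams
  dij <- compute_dij(ph, sp, build_scenarios(mode = "nominal_only"))
  expect_true(all(dij$matrices[[1]]@x >= 0))
  d1 <- dose_vector(dij, 1); d3 <- dose_vector(dij, 3)
  expect_equal(d3, 3 * d1)
  centers <- voxel_centers(ph$grid)
  depth <- (ph$grid$origin_mm[2] + ph$grid$shape[2] * 4) - centers[which.max(d1), 2]
  expect_lt(abs(depth - 100), 4.01)  # within one voxel
})

test_that("scenario columns realize setup shifts and range scaling", {
  ph <- slab_phantom()
  beams <- make_beam_set("explicit", angles = 0)
  sp <- tibble::tibble(id = 1L, field_index = 1L, el_index = 1L,
                       range_mm = 100, peak_wet_mm = 100, lat1_mm = 0, lat2_mm = 0)
  attr(sp, "beams") <- beams
  scen <- build_scenarios(3, 3, "robust")
  dij <- compute_dij(ph, sp, scen)
  centers <- voxel_centers(ph$grid)
  d0 <- dose_vector(dij, 1)
  # +3 mm x setup error: the dose raster translates by -3 mm in patient x
  dx <- dose_vector(dij, 1, which(scen$label == "setup_px"))
  row <- which(abs(centers[, 2] - centers[which.max(d0), 2]) < 1e-9)
  x <- centers[row, 1]
  c0 <- sum(x * d0[row]) / sum(d0[row])
  cx <- sum(x * dx[row]) / sum(dx[row])
  expect_equal(cx - c0, -3, tolerance = 0.05)
  # undershoot (density x1.03): peak depth ~ 100/1.03 (ray-march oracle)
  du <- dose_vector(dij, 1, which(scen$label == "undershoot"))
  depth_u <- (ph$grid$origin_mm[2] + ph$grid$shape[2] * 4) -
    centers[which.max(du), 2]
  expect_lt(abs(depth_u - 100 / 1.03), 4.01)
})

test_that("a range shifter widens the penumbra at matched peak depth", {
  ph <- slab_phantom()
  falloff_80_20 <- function(with_rs) {
    beams <- make_beam_set("explicit", angles = 0, range_shifter = with_rs)
    sp <- tibble::tibble(id = 1L, field_index = 1L, el_index = 1L,
                         range_mm = 100 + if (with_rs) 34 else 0,
                         peak_wet_mm = 100, lat1_mm = 0, lat2_mm = 0)
    attr(sp, "beams") <- beams
    dij <- compute_dij(ph, sp, build_scenarios(mode = "nominal_only"))
    d <- dose_vector(dij, 1)
    centers <- voxel_centers(ph$grid)
    row <- which(abs(centers[, 2] - centers[which.max(d), 2]) < 1e-9)
    prof <- d[row]; x <- centers[row, 1]
    m <- max(prof)
    at <- function(q) {
      i <- max(which(prof >= q * m))
      stats::approx(prof[i:(i + 1)], x[i:(i + 1)], q * m)$y
    }
    at(0.2) - at(0.8)
  }
  expect_gt(falloff_80_20(TRUE), falloff_80_20(FALSE))
})

test_that("a 34 mm range shifter pulls the Bragg peak back by exactly 34 mm", {
  ph <- slab_phantom(depth_mm = 200, target_span = c(80, 120))
  p_no <- bragg_peak_depth(ph, range_mm = 150, range_shifter = FALSE)
  p_rs <- bragg_peak_depth(ph, range_mm = 150, range_shifter = TRUE,
                           rs_wet_mm = 34)
  expect_equal(p_no - p_rs, 34)
})

test_that("dose influence round-trips through the MTX/JSON directory format", {
  ph <- slab_phantom()
  beams <- make_beam_set("explicit", angles = c(0, 90))
  sp <- candidate_spots(ph, beams, 10, 10, 0)
  dij <- compute_dij(ph, sp, build_scenarios(mode = "nominal_only"))
  dir <- withr::local_tempdir()
  write_dij(dij, dir)
  back <- read_dij(dir)
  expect_equal(back$spots$id, dij$spots$id)
  expect_lt(max(abs(back$matrices[[1]] - dij$matrices[[1]])), 1e-12)
  expect_equal(back$grid$spacing_mm, dij$grid$spacing_mm)
})
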