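test_that("MU enforcement removes sub-threshold spots and re-solves in the box", {
  # 2-spot toy: spot 2 sits below mu_min; the re-solve has the closed-form
  # answer w1 = bound / D[1,1] on the surviving spot
  D <- rbind(c(1.0, 0.4), c(0.05, 0.3))
  dij <- protonarc:::toy_dij(D)
  phantom <- protonarc:::toy_phantom(2, list(target = c(TRUE, FALSE),
                                             oar = c(FALSE, TRUE)),
                                     c(target = "target_high", oar = "oar_parallel"))
  wl <- parse_wishlist(list(
    constraints = data.frame(structure = "target", metric = "min_dose",
                             bound = 60, robust = FALSE),
    objectives = data.frame(priority = 1L, structure = "oar",
                            metric = "mean_dose", goal = 0.5,
                            sufficient = FALSE, robust = FALSE)))
  plan <- solve_lexicographic(dij, phantom, wl)
  plan$weights <- stats::setNames(c(59.8, 0.5), c("1", "2"))  # spot 2 < mu_min
  out <- enforce_mu_limits(plan, dij, phantom, wl, mu_min = 1, mu_max = 100)
  expect_equal(unname(out$weights["2"]), 0)
  expect_equal(unname(out$weights["1"]), 60, tolerance = 1e-4)
  nz <- out$weights[out$weights > 0]
  expect_true(all(nz >= 1 - 1e-9 & nz <= 100 + 1e-9))
  # weights already inside the box: plan essentially unchanged
  plan2 <- solve_lexicographic(dij, phantom, wl)
  out2 <- enforce_mu_limits(plan2, dij, phantom, wl, mu_min = 0.01,
                            mu_max = 1000)
  d_before <- as.vector(dij$matrices[[1]] %*%
                          protonarc:::plan_weights_for(plan2, dij))
  d_after <- as.vector(dij$matrices[[1]] %*%
                         protonarc:::plan_weights_for(out2, dij))
  expect_equal(d_after, d_before, tolerance = 1e-3)
  # unreachable mu_min: infeasibility reported
  expect_error(enforce_mu_limits(plan2, dij, phantom, wl, mu_min = 1e5,
                                 mu_max = 2e5),
               class = "protonarc_infeasible")
  expect_error(enforce_mu_limits(plan2, dij, phantom, wl, mu_min = 2,
                                 mu_max = 1), class = "protonarc_spec_error")
})

test_that("normalization rescales to 95% of prescription exactly and is idempotent", {
  # single-scenario toy: VWmin = nominal dose
  D <- rbind(c(0.9, 0.1), c(0.8, 0.5), c(0.1, 1.0))
  dij <- protonarc:::toy_dij(D)
  phantom <- protonarc:::toy_phantom(3, list(target = c(TRUE, TRUE, FALSE)),
                                     c(target = "target_high"))
  plan <- structure(list(weights = stats::setNames(c(50, 30), c("1", "2")),
                         spots = dij$spots, beams = dij$beams, mode = "toy",
                         achieved = NULL,
                         selected_els = dplyr::distinct(dij$spots, field_index,
                                                        el_index)),
                    class = "protonarc_plan")
  d98_before <- dvh_metric(as.vector(dij$matrices[[1]] %*% c(50, 30)),
                           phantom$masks$target, "D98%")
  norm <- normalize_plan(plan, dij, phantom, prescription_gy = 70)
  expect_equal(norm$normalization_scale, 0.95 * 70 / d98_before)
  d98_after <- dvh_metric(as.vector(dij$matrices[[1]] %*%
                                      protonarc:::plan_weights_for(norm, dij)),
                          phantom$masks$target, "D98%")
  expect_equal(d98_after / 70, 0.95, tolerance = 1e-9)
  # idempotence and exact metric scaling
  norm2 <- normalize_plan(norm, dij, phantom, prescription_gy = 70)
  expect_equal(norm2$weights, norm$weights, tolerance = 1e-12)
  s <- norm$normalization_scale
  expect_equal(mean(as.vector(dij$matrices[[1]] %*%
                                protonarc:::plan_weights_for(norm, dij))),
               s * mean(as.vector(dij$matrices[[1]] %*% c(50, 30))),
               tolerance = 1e-12)
  # zero-dose plan cannot be normalized
  zero <- plan; zero$weights[] <- 0
  expect_error(normalize_plan(zero, dij, phantom),
               class = "protonarc_spec_error")
})
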