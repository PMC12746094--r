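test_that("a single active min-dose constraint pins the spot weight", {
  D <- matrix(1 / 30, 1, 1)  # one voxel, one spot, 1/30 Gy per MU
  phantom <- protonarc:::toy_phantom(1, list(target = TRUE),
                                     c(target = "target_high"))
  wl <- parse_wishlist(list(
    constraints = data.frame(structure = "target", metric = "min_dose",
                             bound = 60, robust = FALSE),
    objectives = data.frame(priority = 1L, structure = "target",
                            metric = "mean_dose", goal = 0,
                            sufficient = FALSE, robust = FALSE)))
  dij <- protonarc:::toy_dij(D)
  plan <- solve_lexicographic(dij, phantom, wl)
  expect_equal(unname(plan$weights), 60 / (1 / 30), tolerance = 1e-5)
  expect_equal(plan$achieved$achieved, 60, tolerance = 1e-5)
})

test_that("lexicographic objective vector matches the grid-search oracle", {
  fx <- toy_lp("two_spot_lex")
  plan <- solve_lexicographic(fx$dij, fx$phantom, fx$wishlist, delta = 0.03)
  expect_equal(plan$achieved$achieved, fx$oracle(delta = 0.03),
               tolerance = 1e-2)
  # delta = 0 reduces to strict lexicographic ordering
  plan0 <- solve_lexicographic(fx$dij, fx$phantom, fx$wishlist, delta = 0)
  expect_equal(plan0$achieved$achieved, fx$oracle(delta = 0), tolerance = 1e-2)
  # lexicographic dominance: priority 1 cannot be improved on this support
  expect_gte(plan$achieved$achieved[1], fx$oracle(delta = 0)[1] - 1e-3)
})

test_that("contradictory min/max constraints produce a named infeasibility report", {
  fx <- toy_lp("infeasible_minmax")
  err <- tryCatch(solve_lexicographic(fx$dij, fx$phantom, fx$wishlist),
                  error = function(e) e)
  expect_s3_class(err, "protonarc_infeasible")
  expect_match(conditionMessage(err), "constraint")
  expect_identical(fx$oracle(), "infeasible")
})

test_that("goal values of non-sufficient objectives do not distort the solve", {
  fx <- toy_lp("two_spot_lex")
  tight <- fx$wishlist; tight$objectives$goal <- c(0.1, 0.1)
  loose <- fx$wishlist; loose$objectives$goal <- c(50, 50)
  a <- solve_lexicographic(fx$dij, fx$phantom, tight)
  b <- solve_lexicographic(fx$dij, fx$phantom, loose)
  expect_equal(a$achieved$achieved, b$achieved$achieved, tolerance = 1e-6)
})

test_that("sufficient objectives stop being protected beyond their goal", {
  fx <- toy_lp("two_spot_lex")
  wl <- fx$wishlist
  wl$objectives$sufficient <- c(TRUE, FALSE)
  wl$objectives$goal <- c(20, 1)  # far above the attainable 6
  plan <- solve_lexicographic(fx$dij, fx$phantom, wl, delta = 0)
  # priority 2 may now exploit the slack up to the priority-1 goal
  expect_lte(plan$achieved$achieved[1], 20 + 1e-3)
  expect_lt(plan$achieved$achieved[2], fx$oracle(delta = 0)[2])
})

test_that("per-field dose decomposes the plan and respects trivial cases", {
  D <- rbind(c(0.5, 0.4), c(0.2, 0.9))
  dij <- protonarc:::toy_dij(D, field_index = c(1L, 2L), el_index = c(1L, 1L))
  phantom <- protonarc:::toy_phantom(2, list(target = c(TRUE, TRUE)),
                                     c(target = "target_high"))
  plan <- structure(list(weights = stats::setNames(c(10, 20), c("1", "2")),
                         spots = dij$spots, beams = dij$beams, mode = "toy",
                         selected_els = dplyr::distinct(dij$spots, field_index,
                                                        el_index)),
                    class = "protonarc_plan")
  expect_equal(per_field_max_dose(plan, dij, 1), max(D[, 1] * 10))
  expect_equal(per_field_max_dose(plan, dij, 2), max(D[, 2] * 20))
  zero <- plan; zero$weights[] <- 0
  expect_equal(per_field_max_dose(zero, dij, 1), 0)
  # single-field plan: per-field max equals the whole-plan max dose
  one <- plan; one$weights[2] <- 0
  expect_equal(per_field_max_dose(one, dij, 1),
               max(as.vector(dij$matrices[[1]] %*% c(10, 0))))
  expect_error(per_field_max_dose(plan, dij, 9), class = "protonarc_spec_error")
})

test_that("hard constraints hold in every declared scenario after a solve", {
  res <- cached_cs4()
  ph <- cached_default_phantom()
  dij <- res$dij  # 21-scenario dose influence on the final support
  beams <- dij$beams
  wl <- parse_wishlist(default_wishlist())
  plan <- solve_lexicographic(dij, ph, wl)
  w <- protonarc:::plan_weights_for(plan, dij)
  for (ci in seq_len(nrow(wl$constraints))) {
    cc <- wl$constraints[ci, ]
    if (cc$metric == "per_field_max_dose") {
      for (f in beams$field_index)
        expect_lte(per_field_max_dose(plan, dij, f), cc$bound + 1e-3)
      next
    }
    vox <- which(as.vector(ph$masks[[cc$structure]]))
    scen <- if (cc$robust) seq_len(nrow(dij$scenarios)) else 1L
    for (s in scen) {
      d <- as.vector(dij$matrices[[s]][vox, , drop = FALSE] %*% w)
      if (cc$metric == "min_dose") expect_gte(min(d), cc$bound - 1e-3)
      if (cc$metric == "max_dose") expect_lte(max(d), cc$bound + 1e-3)
    }
  }
})
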