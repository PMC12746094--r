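test_that("energy-layer groups partition the spot set and match a grouping oracle", {
  # 36 fields x 10 ELs x 4 lateral spots -> 360 groups of 4
  big <- tibble::tibble(id = 1:1440,
                        field_index = rep(1:36, each = 40),
                        el_index = rep(rep(1:10, each = 4), times = 36))
  g <- build_el_groups(big)
  expect_identical(nrow(g), 360L)
  expect_true(all(g$n_members == 4L))
  expect_identical(sort(unlist(g$member_ids, use.names = FALSE)), big$id)
  # single spot
  g1 <- build_el_groups(tibble::tibble(id = 7L, field_index = 2L, el_index = 5L))
  expect_identical(nrow(g1), 1L)
  # random spot table vs independent key-grouping oracle
  set.seed(9)
  rnd <- tibble::tibble(id = sample(1000, 60),
                        field_index = sample(1:4, 60, TRUE),
                        el_index = sample(1:5, 60, TRUE))
  g2 <- build_el_groups(rnd)
  mem <- attr(g2, "membership")
  oracle <- as.integer(factor(paste(rnd$field_index, rnd$el_index),
                              levels = unique(paste(rnd$field_index, rnd$el_index))))
  expect_identical(mem, oracle)
  expect_identical(sum(g2$n_members), 60L)
})

test_that("a uniquely sufficient energy layer survives heavy regularization", {
  fx <- toy_lp("one_el_sufficient")
  orc <- fx$oracle()
  expect_identical(orc$minimal, "2")  # exhaustive subset enumeration
  g <- build_el_groups(fx$dij$spots)
  res <- reduce_energy_layers(fx$dij, fx$phantom, fx$wishlist, g, lambda = 10)
  expect_identical(res$selected_els$el_index, 2L)
  # the surviving support still satisfies the constraints downstream
  plan <- solve_lexicographic(fx$dij, fx$phantom, fx$wishlist,
                              support = res$selected_ids)
  w <- protonarc:::plan_weights_for(plan, fx$dij)
  d <- as.vector(fx$dij$matrices[[1]] %*% w)
  expect_gte(d[1], 60 - 1e-3)
  expect_lte(d[2], 20 + 1e-3)
})

test_that("lambda = 0 reproduces the unpenalized optimum exactly", {
  toy <- elr_toy()
  res0 <- reduce_energy_layers(toy$dij, toy$phantom, toy$wishlist, lambda = 0)
  plain <- solve_surrogate(toy$dij, toy$phantom, toy$wishlist)
  expect_equal(res0$objective, plain$objective, tolerance = 1e-8)
  expect_identical(sort(res0$selected_ids),
                   sort(toy$dij$spots$id[plain$weights >
                                           1e-3 * max(plain$weights)]))
})

test_that("EL count falls and plan quality degrades monotonically with lambda", {
  toy <- elr_toy()
  lambdas <- 10^seq(-3, 2)
  counts <- integer(0); objs <- numeric(0)
  for (lam in lambdas) {
    r <- reduce_energy_layers(toy$dij, toy$phantom, toy$wishlist, lambda = lam)
    counts <- c(counts, nrow(r$selected_els))
    objs <- c(objs, surrogate_objective(toy$dij, toy$phantom, toy$wishlist,
                                        support = r$selected_ids))
  }
  expect_true(all(diff(counts) <= 0L))
  expect_true(all(diff(objs) >= -1e-6))
  expect_identical(counts[1], 3L)   # narrow layers win unpenalized
  expect_identical(counts[length(counts)], 1L)  # broad layer wins penalized
})

test_that("the coefficient tuner agrees with a dense log-grid scan", {
  toy <- elr_toy()
  lam <- tune_lambda(toy$dij, toy$phantom, toy$wishlist,
                     target_mean_els = 1, bracket = c(1e-3, 100))
  expect_identical(attr(lam, "el_count"), 1L)
  # dense scan oracle: the tuned lambda sits in the region the scan marks
  grid_l <- 10^seq(-3, 2, length.out = 26)
  cnt <- vapply(grid_l, function(l) nrow(reduce_energy_layers(
    toy$dij, toy$phantom, toy$wishlist, lambda = l)$selected_els), integer(1))
  ok <- grid_l[cnt == 1L]
  step <- grid_l[2] / grid_l[1]
  expect_true(as.numeric(lam) >= min(ok) / step &&
                as.numeric(lam) <= max(ok) * step)
  # bracket-end conventions
  lam_all <- tune_lambda(toy$dij, toy$phantom, toy$wishlist,
                         target_mean_els = 3, bracket = c(1e-3, 100))
  expect_equal(as.numeric(lam_all), 1e-3)
  expect_error(tune_lambda(toy$dij, toy$phantom, toy$wishlist,
                           target_mean_els = 99, bracket = c(1e-3, 100)),
               class = "protonarc_bracket_error")
})

test_that("singleton groups make the group penalty behave like L1 selection", {
  toy <- siss_toy()
  groups <- build_el_groups(toy$dij$spots)  # toy_dij: one EL per spot
  expect_true(all(groups$n_members == 1L))
  lam <- 1
  res <- reduce_energy_layers(toy$dij, toy$phantom, toy$wishlist, groups,
                              lambda = lam)
  l1 <- select_spots(toy$dij, toy$phantom, toy$wishlist, lam)
  expect_identical(sort(res$selected_ids), sort(as.integer(l1)))
})
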