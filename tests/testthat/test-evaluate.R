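test_that("DVH metrics match closed forms and a sort-and-scan oracle", {
  m <- rep(TRUE, 4)
  expect_equal(dvh_metric(rep(70, 4), m, "D98%"), 70)
  expect_equal(dvh_metric(rep(70, 4), m, "Dmean"), 70)
  expect_equal(dvh_metric(c(60, 60, 70, 70), m, "Dmean"), 65)
  expect_equal(dvh_metric(c(60, 60, 70, 70), m, "V65Gy"), 0.5)
  set.seed(11)
  d <- stats::runif(1000, 0, 80)
  for (q in c(2, 50, 98))
    expect_equal(dvh_metric(d, rep(TRUE, 1000), sprintf("D%d%%", q)),
                 oracle_dq(d, q), tolerance = 1e-9)
  expect_error(dvh_metric(d, rep(FALSE, 1000), "D98%"),
               class = "protonarc_spec_error")
  expect_error(dvh_metric(d, rep(TRUE, 1000), "Q5"),
               class = "protonarc_spec_error")
})

test_that("NTCP is logistic in its predictors and bounded in (0,1)", {
  model <- list(name = "toy", intercept = -1, terms = data.frame(
    predictor = c("parotid_mean", "baseline"),
    transform = c("sqrt", "identity"),
    coefficient = c(0.25, 1)))
  # linear predictor 0 -> 0.5
  expect_equal(ntcp(list(parotid_mean = 0), model), stats::plogis(0))
  # zero dose -> logistic(intercept + baseline terms)
  m2 <- model; m2$terms$coefficient <- c(0.25, 0.3)
  expect_equal(ntcp(list(parotid_mean = 0), m2), stats::plogis(-0.7))
  # strictly increasing in a positive-coefficient dose predictor
  vals <- vapply(seq(0, 60, by = 5), function(dm)
    ntcp(list(parotid_mean = dm), model), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_error(ntcp(list(), model), class = "protonarc_spec_error")
  # the shipped illustrative model file loads and stays in (0,1)
  models <- load_ntcp_models()
  expect_true(all(c("name", "grade", "intercept", "terms") %in%
                    names(models[[1]])))
  p <- ntcp(list(parotid_l_mean = 20, parotid_r_mean = 20,
                 constrictor_mean = 30), models$xerostomia_g2)
  expect_true(p > 0 && p < 1)
})

test_that("integral dose equals the dense summation oracle", {
  g <- grid_spec(c(10, 10, 10), c(10, 10, 10))  # 1 L total
  mask <- array(TRUE, dim = g$shape)
  expect_equal(integral_dose(array(2, dim = g$shape), mask, g), 2)
  expect_equal(integral_dose(array(0, dim = g$shape), mask, g), 0)
  set.seed(3)
  d <- array(stats::runif(1000), dim = g$shape)
  mask[sample(1000, 400)] <- FALSE
  acc <- 0
  for (v in which(mask)) acc <- acc + d[v] * 1000 / 1e6
  expect_equal(integral_dose(d, mask, g), acc, tolerance = 1e-12)
})

test_that("exact signed-rank p-values match exhaustive sign-flip enumeration", {
  # n = 10, all positive: the familiar two-sided floor p of 2/2^10
  all_pos <- wilcoxon_signed_rank_exact(rep(1, 10) + (1:10) / 100)
  expect_equal(all_pos$p_value, 2 / 1024, tolerance = 1e-12)
  # identical pairs: degenerate, p = 1 under the zero-drop policy
  expect_equal(wilcoxon_signed_rank_exact(numeric(10))$p_value, 1)
  # one negative small-rank difference
  d <- c(-0.05, 0.2, 0.3, 0.45, 0.6, 0.7, 0.8, 0.9, 1.1, 1.2)
  expect_equal(wilcoxon_signed_rank_exact(d)$p_value, oracle_wilcoxon(d),
               tolerance = 1e-12)
  # random cases incl. ties and zeros vs the enumeration oracle
  set.seed(21)
  for (i in 1:6) {
    d <- round(stats::rnorm(sample(5:11, 1)), 1)
    expect_equal(wilcoxon_signed_rank_exact(d)$p_value, oracle_wilcoxon(d),
                 tolerance = 1e-12, label = paste(d, collapse = ","))
  }
})

test_that("paired comparisons are antisymmetric with symmetric p-values", {
  set.seed(5)
  a <- tibble::tibble(phantom = rep(1:8, 2),
                      metric = rep(c("m1", "m2"), each = 8),
                      value = stats::runif(16, 10, 20))
  b <- a; b$value <- a$value - c(rep(0.5, 8), stats::rnorm(8, 0, 0.2))
  ab <- compare_plans(a, b); ba <- compare_plans(b, a)
  expect_equal(ab$median_diff, -ba$median_diff)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(ab$significant[ab$metric == "m1"])  # 8 one-sided shifts
  same <- compare_plans(a, a)
  expect_true(all(same$p_value == 1) && all(!same$significant))
  expect_error(compare_plans(a, b[-1, ]), class = "protonarc_spec_error")
})

test_that("evaluation reports are internally consistent", {
  # robust-bracketing of D98 and the summed-NTCP aggregate
  res <- cached_cs4()
  ph <- cached_default_phantom()
  ev <- res$report
  for (nm in c("ctv70", "ctv5425")) {
    msk <- ph$masks[[nm]]
    d98n <- dvh_metric(ev$dose_nominal, msk, "D98%")
    expect_lte(dvh_metric(ev$dose_vwmin, msk, "D98%"), d98n + 1e-9)
    expect_lte(d98n, dvh_metric(ev$dose_vwmax, msk, "D98%") + 1e-9)
  }
  expect_true(all(ev$ntcp$ntcp > 0 & ev$ntcp$ntcp < 1))
  expect_equal(ev$summary$summed_ntcp_g2,
               sum(ev$ntcp$ntcp[ev$ntcp$grade == "g2"]))
  expect_equal(ev$summary$summed_ntcp_g3,
               sum(ev$ntcp$ntcp[ev$ntcp$grade == "g3"]))
  td <- tidy(ev)
  expect_true(all(c("structure", "metric", "value") %in% names(td)))
  expect_s3_class(glance(ev), "tbl_df")
  expect_s3_class(plot_dvh(ev, ph), "ggplot")
  expect_s3_class(ggplot2::autoplot(res$plan), "ggplot")
  expect_s3_class(ggplot2::autoplot(ph), "ggplot")
})
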