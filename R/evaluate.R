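# Plan evaluation: DVH metrics, NTCP models, integral dose, and paired
# statistical comparison between planning modes.

#' Dose-volume histogram metric
#'
#' `D{q}%` is the dose level such that q percent of the structure's volume
#' receives at least that dose (descending sort, index `ceiling(q/100 * n)`,
#' no sub-voxel interpolation); `Dmean` the volume-weighted mean;
#' `V{x}Gy` the fractional volume receiving at least x Gy.
#'
#' @param dose dose raster (array or vector over voxels).
#' @param mask logical mask (same shape) or voxel index vector.
#' @param metric e.g. `"D98%"`, `"Dmean"`, `"V65Gy"`, `"D2%"`.
#' @return the metric value (Gy, or a fraction in 0..1 for V-metrics).
#' @export
#' @examples
#' dvh_metric(c(60, 70, 70, 70), rep(TRUE, 4), "Dmean")
dvh_metric <- function(dose, mask, metric) {
  d <- if (is.logical(mask) || is.array(mask)) as.vector(dose)[as.vector(mask)]
       else as.vector(dose)[mask]
  if (!length(d))
    stop_protonarc("empty structure mask", "protonarc_spec_error")
  if (metric == "Dmean") return(mean(d))
  m <- regmatches(metric, regexec("^D([0-9.]+)%$", metric))[[1]]
  if (length(m)) {
    q <- as.numeric(m[2])
    sd_ <- sort(d, decreasing = TRUE)
    return(sd_[max(1L, min(length(d), ceiling(q / 100 * length(d))))])
  }
  m <- regmatches(metric, regexec("^V([0-9.]+)Gy$", metric))[[1]]
  if (length(m)) return(mean(d >= as.numeric(m[2])))
  stop_protonarc(sprintf("unknown DVH metric '%s'", metric), "protonarc_spec_error")
}

#' Normal tissue complication probability from a logistic model
#'
#' `NTCP = logistic(intercept + sum coefficient * transform(predictor))`
#' with transforms `identity` or `sqrt`. A predictor named `"baseline"`
#' always takes the value 1 (baseline covariates folded into the linear
#' predictor).
#'
#' @param predictors named list/vector of predictor values (dose metrics in
#'   Gy).
#' @param model list with `name`, `intercept`, and `terms` (data frame with
#'   `predictor`, `transform`, `coefficient`).
#' @return probability in (0, 1).
#' @export
ntcp <- function(predictors, model) {
  terms <- as.data.frame(model$terms)
  s <- model$intercept
  for (i in seq_len(nrow(terms))) {
    pn <- terms$predictor[i]
    v <- if (pn == "baseline") 1 else predictors[[pn]]
    if (is.null(v) || is.na(v))
      stop_protonarc(sprintf("NTCP model '%s': missing predictor '%s'",
                             model$name, pn), "protonarc_spec_error")
    tv <- switch(terms$transform[i], identity = v, sqrt = sqrt(v),
                 stop_protonarc(sprintf("unknown transform '%s'", terms$transform[i]),
                                "protonarc_spec_error"))
    s <- s + terms$coefficient[i] * tv
  }
  stats::plogis(s)
}

#' Load NTCP models from JSON
#'
#' The shipped `ntcp_models.json` contains illustrative logistic models for
#' grade 2/3 xerostomia and dysphagia (plausible structure and signs, not
#' published protocol coefficients).
#'
#' @param path JSON file; defaults to the shipped illustrative set.
#' @return named list of model lists, each tagged with its toxicity grade.
#' @export
load_ntcp_models <- function(path = system.file("extdata", "ntcp_models.json",
                                                package = "protonarc")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  models <- lapply(seq_len(nrow(raw$models)), function(i) {
    list(name = raw$models$name[i], grade = raw$models$grade[i],
         intercept = raw$models$intercept[i],
         terms = raw$models$terms[[i]])
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "name"))
}

#' Integral dose over a volume
#'
#' @param dose dose raster (Gy).
#' @param mask body mask (logical raster).
#' @param grid the `protonarc_grid`.
#' @return integral dose in Gy L.
#' @export
integral_dose <- function(dose, mask, grid) {
  sum(as.vector(dose)[as.vector(mask)]) * prod(grid$spacing_mm) / 1e6
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired-difference policy: zero differences are dropped; tied absolute
#' differences receive mid-ranks. For n <= 25 (after zero-dropping) the
#' null distribution of the signed-rank statistic is enumerated exactly by
#' convolution over sign flips (mid-ranks doubled to integers); beyond
#' that, a normal approximation with tie correction is used. With no
#' non-zero differences, p = 1 by convention.
#'
#' @param d numeric vector of paired differences.
#' @return list with `statistic` (W+, sum of positive ranks), `n_used`,
#'   `p_value`, `method`.
#' @export
wilcoxon_signed_rank_exact <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, n_used = 0L, p_value = 1,
                          method = "degenerate (all zero differences)"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)  # counts over achievable doubled statistics
    f[1] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1):(total + 1)] <- g[(rr + 1):(total + 1)] + f[1:(total + 1 - rr)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    lower <- sum(probs[seq_len(w2 + 1)])
    upper <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(lower, upper))
    list(statistic = w, n_used = n, p_value = p, method = "exact enumeration")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    list(statistic = w, n_used = n, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Paired comparison of plan metrics between two modes
#'
#' For every metric present in both inputs, computes the median paired
#' difference (A - B) and the exact two-sided Wilcoxon signed-rank p-value.
#'
#' @param a,b either numeric vectors (one metric, paired by position) or
#'   long-format data frames with columns `phantom`, `metric`, `value`,
#'   paired on (phantom, metric).
#' @param alpha significance level (default 0.05).
#' @return tibble with `metric`, `n`, `median_diff`, `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_plans <- function(a, b, alpha = 0.05) {
  if (is.numeric(a) && is.numeric(b)) {
    a <- tibble::tibble(phantom = seq_along(a), metric = "value", value = a)
    b <- tibble::tibble(phantom = seq_along(b), metric = "value", value = b)
  }
  j <- dplyr::inner_join(a, b, by = c("phantom", "metric"),
                         suffix = c("_a", "_b"))
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b))
    stop_protonarc("inputs are not fully paired on (phantom, metric)",
                   "protonarc_spec_error")
  j |>
    dplyr::group_by(metric) |>
    dplyr::group_modify(function(df, key) {
      d <- df$value_a - df$value_b
      wt <- wilcoxon_signed_rank_exact(d)
      tibble::tibble(n = length(d), median_diff = stats::median(d),
                     statistic = wt$statistic, p_value = wt$p_value,
                     significant = wt$p_value < alpha)
    }) |>
    dplyr::ungroup()
}

#' Evaluate a finalized plan
#'
#' Computes, per structure: nominal mean dose, D98% of the voxel-wise
#' minimum (robust coverage), and the near-maximum dose (by convention
#' D2% of the voxel-wise maximum). Adds NTCP values for the configured
#' logistic models (dose predictors named `<structure>_mean`), the integral
#' dose over the body (nothing excluded), and plan delivery counts.
#'
#' @param plan a `protonarc_plan`.
#' @param dij the dose-influence set (all scenarios used for VWmin/VWmax).
#' @param phantom the phantom.
#' @param ntcp_models named list from [load_ntcp_models()] (NULL to skip).
#' @param near_max_metric DVH metric for the near-maximum (default
#'   `"D2%"`).
#' @return a `protonarc_eval`: list with `structures` (metric tibble),
#'   `ntcp` (tibble with per-model probabilities and per-grade sums),
#'   `summary` (one-row tibble), and the nominal/VWmin/VWmax dose rasters.
#' @export
evaluate_plan <- function(plan, dij, phantom, ntcp_models = NULL,
                          near_max_metric = "D2%") {
  w <- plan_weights_for(plan, dij)
  doses <- lapply(seq_len(nrow(dij$scenarios)), function(s) dose_vector(dij, w, s))
  nominal <- doses[[1]]
  vwmin <- voxelwise_aggregate(doses, "min")
  vwmax <- voxelwise_aggregate(doses, "max")
  snames <- names(phantom$masks)
  st <- dplyr::bind_rows(lapply(snames, function(nm) {
    msk <- phantom$masks[[nm]]
    tibble::tibble(
      structure = nm, role = unname(phantom$roles[[nm]]),
      dmean_gy = dvh_metric(nominal, msk, "Dmean"),
      d98_vwmin_gy = dvh_metric(vwmin, msk, "D98%"),
      near_max_vwmax_gy = dvh_metric(vwmax, msk, near_max_metric))
  }))
  ntcp_tbl <- NULL
  if (!is.null(ntcp_models)) {
    preds <- stats::setNames(as.list(st$dmean_gy), paste0(st$structure, "_mean"))
    ntcp_tbl <- dplyr::bind_rows(lapply(ntcp_models, function(m)
      tibble::tibble(model = m$name, grade = m$grade,
                     ntcp = ntcp(preds, m))))
  }
  summ <- tibble::tibble(
    mode = plan$mode,
    integral_dose_gy_l = integral_dose(nominal, phantom$masks$body, dij$grid),
    n_spots = sum(plan$weights > 1e-9),
    n_els = nrow(plan$selected_els),
    total_mu = sum(plan$weights),
    wishlist_digest = plan$wishlist_digest)
  if (!is.null(ntcp_tbl)) {
    sums <- tapply(ntcp_tbl$ntcp, ntcp_tbl$grade, sum)
    for (g in names(sums)) summ[[paste0("summed_ntcp_", g)]] <- unname(sums[[g]])
  }
  structure(list(structures = st, ntcp = ntcp_tbl, summary = summ,
                 dose_nominal = nominal, dose_vwmin = vwmin, dose_vwmax = vwmax,
                 grid = dij$grid),
            class = "protonarc_eval")
}

#' @exportS3Method base::print
print.protonarc_eval <- function(x, ...) {
  cat("<protonarc_eval>\n")
  print(as.data.frame(x$structures), digits = 4)
  if (!is.null(x$ntcp)) print(as.data.frame(x$ntcp), digits = 4)
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @rdname evaluate_plan
#' @param x a `protonarc_eval`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.protonarc_eval <- function(x, ...) {
  long <- tidyr::pivot_longer(x$structures, -c(structure, role),
                              names_to = "metric", values_to = "value")
  if (!is.null(x$ntcp))
    long <- dplyr::bind_rows(long, tibble::tibble(
      structure = x$ntcp$model, role = "ntcp_model",
      metric = paste0("ntcp_", x$ntcp$grade), value = x$ntcp$ntcp))
  long
}

#' @rdname evaluate_plan
#' @exportS3Method generics::glance
glance.protonarc_eval <- function(x, ...) x$summary

#' Cumulative DVH table of an evaluation
#'
#' @param eval_ a `protonarc_eval`.
#' @param structures structure names (default: all non-body, non-blocking).
#' @param which raster: `"nominal"`, `"vwmin"` or `"vwmax"`.
#' @param phantom the phantom (for masks).
#' @return tibble `structure`, `dose_gy`, `volume_fraction`.
#' @export
dvh_table <- function(eval_, phantom, structures = NULL, which = "nominal") {
  if (is.null(structures))
    structures <- names(phantom$masks)[!phantom$roles %in% c("body", "blocking")]
  dose <- switch(which, nominal = eval_$dose_nominal,
                 vwmin = eval_$dose_vwmin, vwmax = eval_$dose_vwmax)
  grid_d <- seq(0, max(dose) * 1.02 + 1e-9, length.out = 120)
  dplyr::bind_rows(lapply(structures, function(nm) {
    d <- as.vector(dose)[as.vector(phantom$masks[[nm]])]
    tibble::tibble(structure = nm, dose_gy = grid_d,
                   volume_fraction = vapply(grid_d, function(t) mean(d >= t),
                                            numeric(1)))
  }))
}

#' Plot cumulative DVHs
#'
#' @inheritParams dvh_table
#' @return a ggplot object.
#' @export
plot_dvh <- function(eval_, phantom, structures = NULL, which = "nominal") {
  tbl <- dvh_table(eval_, phantom, structures, which)
  ggplot2::ggplot(tbl, ggplot2::aes(dose_gy, volume_fraction, colour = structure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose [Gy_RBE]", y = "Volume fraction ≥ dose",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phantom slice with structure contours
#'
#' @param object a `protonarc_phantom`.
#' @param slice axial slice index (1-based).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.protonarc_phantom <- function(object, slice = 1L, ...) {
  g <- object$grid
  centers <- voxel_centers(g)
  idx <- seq_len(g$shape[1] * g$shape[2]) + (slice - 1L) * g$shape[1] * g$shape[2]
  df <- tibble::tibble(x = centers[idx, 1], y = centers[idx, 2],
                       density = as.vector(object$density)[idx])
  masks <- dplyr::bind_rows(lapply(names(object$masks), function(nm)
    tibble::tibble(x = centers[idx, 1], y = centers[idx, 2], structure = nm,
                   inside = as.vector(object$masks[[nm]])[idx])))
  ggplot2::ggplot(df, ggplot2::aes(x, y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = density)) +
    ggplot2::geom_contour(data = masks[masks$structure != "body", ],
                          ggplot2::aes(z = as.numeric(inside), colour = structure),
                          breaks = 0.5, linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "black", high = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]") +
    ggplot2::theme_minimal()
}

#' Plot per-field monitor units of a plan
#'
#' @param object a `protonarc_plan`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.protonarc_plan <- function(object, ...) {
  df <- tibble::tibble(field_index = object$spots$field_index,
                       weight = unname(object$weights))
  df <- dplyr::summarise(dplyr::group_by(df, field_index),
                         mu = sum(weight), .groups = "drop")
  df <- dplyr::left_join(df, object$beams, by = "field_index")
  ggplot2::ggplot(df, ggplot2::aes(gantry_deg, mu)) +
    ggplot2::geom_col(width = 4) +
    ggplot2::labs(x = "Gantry angle [deg]", y = "Field MU") +
    ggplot2::theme_minimal()
}
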