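# Wish-list driven multi-criteria optimization: lexicographic
# (epsilon-constraint) spot-weight optimization over scenario-dependent
# dose, plus the scalarized surrogate used by the sparsification stages.

wl_check_structures <- function(wishlist, phantom) {
  used <- unique(c(wishlist$constraints$structure, wishlist$objectives$structure))
  unknown <- setdiff(used, names(phantom$masks))
  if (length(unknown))
    stop_protonarc(sprintf("wish-list names unknown structure(s): %s",
                           paste(unknown, collapse = ", ")),
                   "protonarc_spec_error")
}

# Mean-dose row (length n) for a structure in one scenario.
mean_dose_row <- function(dij, vox, s) {
  Matrix::colMeans(dij$matrices[[s]][vox, , drop = FALSE])
}

#' Evaluate a wish-list metric for given spot weights
#'
#' Robust metrics take the worst case over all scenarios in the dose
#' influence set; non-robust metrics use the nominal (first) scenario.
#'
#' @param dij a `protonarc_dij`.
#' @param phantom the phantom.
#' @param structure structure name.
#' @param metric `"mean_dose"` or `"max_dose"`.
#' @param w spot weights aligned with `dij$spots`.
#' @param robust logical.
#' @return the metric value in Gy_RBE.
#' @export
metric_value <- function(dij, phantom, structure, metric, w, robust = FALSE) {
  vox <- which(as.vector(phantom$masks[[structure]]))
  scen <- if (robust) seq_len(nrow(dij$scenarios)) else 1L
  vals <- vapply(scen, function(s) {
    d <- as.vector(dij$matrices[[s]][vox, , drop = FALSE] %*% w)
    if (metric == "mean_dose") mean(d) else max(d)
  }, numeric(1))
  max(vals)
}

# --- constraint families (width n = number of spots) ------------------------

# Cutting-plane family for voxel-wise dose bounds: sense +1 keeps dose >= b
# (min dose), sense -1 keeps dose <= b (max dose).
dose_bound_family <- function(dij, vox, scen_idx, bound, sense, label,
                              K = 40, tol = 1e-4) {
  force(bound); force(sense); force(label); force(K); force(tol)
  subs <- lapply(scen_idx, function(s) dij$matrices[[s]][vox, , drop = FALSE])
  list(label = label, fn = function(x) {
    rows <- list(); rhs <- list()
    for (k in seq_along(subs)) {
      d <- as.vector(subs[[k]] %*% x)
      viol <- if (sense > 0) d < bound - tol else d > bound + tol
      if (!any(viol)) next
      exc <- if (sense > 0) bound - d else d - bound
      ord <- which(viol)[order(exc[viol], decreasing = TRUE)]
      ord <- ord[seq_len(min(K, length(ord)))]
      rows[[length(rows) + 1L]] <- sense * as.matrix(subs[[k]][ord, , drop = FALSE])
      rhs[[length(rhs) + 1L]] <- rep(sense * bound, length(ord))
    }
    if (!length(rows)) return(NULL)
    list(rows = do.call(rbind, rows), rhs = unlist(rhs))
  })
}

# Per-field voxel-wise cap family (nominal scenario).
per_field_cap_family <- function(dij, bound, label, K = 20, tol = 1e-4) {
  force(bound); force(label); force(K); force(tol)
  m1 <- dij$matrices[[1]]
  fields <- unique(dij$spots$field_index)
  cols <- lapply(fields, function(f) which(dij$spots$field_index == f))
  list(label = label, fn = function(x) {
    rows <- list(); rhs <- list()
    for (k in seq_along(fields)) {
      cf <- cols[[k]]
      d <- as.vector(m1[, cf, drop = FALSE] %*% x[cf])
      viol <- which(d > bound + tol)
      if (!length(viol)) next
      viol <- viol[order(d[viol], decreasing = TRUE)]
      viol <- viol[seq_len(min(K, length(viol)))]
      r <- matrix(0, length(viol), ncol(m1))
      r[, cf] <- -as.matrix(m1[viol, cf, drop = FALSE])
      rows[[length(rows) + 1L]] <- r
      rhs[[length(rhs) + 1L]] <- rep(-bound, length(viol))
    }
    if (!length(rows)) return(NULL)
    list(rows = do.call(rbind, rows), rhs = unlist(rhs))
  })
}

# Compile the wish-list's hard constraints into fixed rows + families.
hard_constraint_set <- function(dij, phantom, wishlist, tol = 1e-4) {
  n <- nrow(dij$spots)
  fixed <- new_pool(n)
  fams <- list()
  cons <- wishlist$constraints
  for (ci in seq_len(nrow(cons))) {
    cc <- cons[ci, ]
    lab <- sprintf("constraint %d: %s %s %s %.4g Gy", ci, cc$structure, cc$metric,
                   if (cc$metric == "min_dose") ">=" else "<=", cc$bound)
    scen_idx <- if (cc$robust) seq_len(nrow(dij$scenarios)) else 1L
    if (cc$metric == "mean_dose") {
      for (s in scen_idx) {
        vox <- which(as.vector(phantom$masks[[cc$structure]]))
        fixed <- pool_add(fixed, matrix(-mean_dose_row(dij, vox, s), 1), -cc$bound, lab)
      }
    } else if (cc$metric == "per_field_max_dose") {
      fams[[length(fams) + 1L]] <- per_field_cap_family(dij, cc$bound, lab, tol = tol)
    } else {
      vox <- which(as.vector(phantom$masks[[cc$structure]]))
      sense <- if (cc$metric == "min_dose") 1 else -1
      fams[[length(fams) + 1L]] <-
        dose_bound_family(dij, vox, scen_idx, cc$bound, sense, lab, tol = tol)
    }
  }
  list(fixed = fixed, families = fams)
}

# Pad width-n rows/families to width nvar (aux columns appended).
pad_rows <- function(rows, nvar) cbind(rows, matrix(0, nrow(rows), nvar - ncol(rows)))
pad_family <- function(fam, n, nvar) {
  force(fam); force(n); force(nvar)
  list(label = fam$label, fn = function(x) {
    v <- fam$fn(x[seq_len(n)])
    if (is.null(v)) return(NULL)
    list(rows = pad_rows(v$rows, nvar), rhs = v$rhs)
  })
}

# Aux-linking family for a max-dose objective: dose_v <= t (t = column tcol).
aux_max_family <- function(dij, vox, scen_idx, n, nvar, tcol, K = 40, tol = 1e-4) {
  force(n); force(nvar); force(tcol); force(K); force(tol)
  subs <- lapply(scen_idx, function(s) dij$matrices[[s]][vox, , drop = FALSE])
  list(label = "aux", fn = function(x) {
    t <- x[tcol]
    rows <- list(); rhs <- list()
    for (k in seq_along(subs)) {
      d <- as.vector(subs[[k]] %*% x[seq_len(n)])
      viol <- which(d > t + tol)
      if (!length(viol)) next
      viol <- viol[order(d[viol], decreasing = TRUE)]
      viol <- viol[seq_len(min(K, length(viol)))]
      r <- matrix(0, length(viol), nvar)
      r[, seq_len(n)] <- -as.matrix(subs[[k]][viol, , drop = FALSE])
      r[, tcol] <- 1
      rows[[length(rows) + 1L]] <- r
      rhs[[length(rhs) + 1L]] <- rep(0, length(viol))
    }
    if (!length(rows)) return(NULL)
    list(rows = do.call(rbind, rows), rhs = unlist(rhs))
  })
}

# --- lexicographic solve ----------------------------------------------------

#' Solve the wish-list's lexicographic multi-criteria problem
#'
#' Sequential per-priority epsilon-constraint solves: objective k is
#' minimized subject to (a) all hard constraints (robust items in every
#' scenario of `dij`, the per-field cap in the nominal scenario), (b) the
#' previously optimized objectives bounded at their achieved value times
#' (1 + `delta`) (objectives marked `sufficient` are bounded at their goal
#' once the goal is reached), (c) nonnegative weights, and (d) an optional
#' sparsity penalty added to every stage's cost. Each stage is a strictly
#' convex QP (see the solver core); the result is Pareto-optimal with
#' respect to the prioritized objective vector on the given support.
#'
#' @param dij a `protonarc_dij` covering all scenarios the wish-list's
#'   robust items need.
#' @param phantom the phantom.
#' @param wishlist a `protonarc_wishlist`.
#' @param support optional spot id subset to optimize over.
#' @param extra_penalty optional list `(kind = "l1"|"group", coefficient,
#'   groups)`; `groups` is an integer vector over the (restricted) spots.
#' @param delta slack factor applied when bounding attained objectives
#'   (default 0.03).
#' @param ridge Tikhonov ridge of the QP stages.
#' @param tol constraint tolerance (Gy).
#' @param mode label stored on the plan.
#' @return a `protonarc_plan`: spot weights, support, achieved objective
#'   values per priority, beams, wish-list digest.
#' @export
solve_lexicographic <- function(dij, phantom, wishlist, support = NULL,
                                extra_penalty = NULL, delta = 0.03,
                                ridge = 1e-7, tol = 1e-4, mode = "custom") {
  wl_check_structures(wishlist, phantom)
  if (!is.null(support)) dij <- dij_subset(dij, support)
  n <- nrow(dij$spots)
  if (!n) stop_protonarc("empty spot support", "protonarc_spec_error")
  hc <- hard_constraint_set(dij, phantom, wishlist, tol = tol)
  spot_pool <- hc$fixed
  obj <- wishlist$objectives
  achieved <- numeric(nrow(obj))
  l1 <- 0; groups <- NULL; lambda <- 0
  if (!is.null(extra_penalty)) {
    if (extra_penalty$kind == "l1") l1 <- extra_penalty$coefficient
    else { groups <- extra_penalty$groups; lambda <- extra_penalty$coefficient }
  }
  x <- NULL
  for (k in seq_len(nrow(obj))) {
    ob <- obj[k, ]
    vox <- which(as.vector(phantom$masks[[ob$structure]]))
    scen_idx <- if (ob$robust) seq_len(nrow(dij$scenarios)) else 1L
    use_aux <- ob$metric == "max_dose" || (ob$metric == "mean_dose" && ob$robust)
    nvar <- n + as.integer(use_aux)
    lin <- numeric(nvar)
    stage_pool <- new_pool(nvar)
    if (nrow(spot_pool$rows))
      stage_pool <- pool_add(stage_pool, pad_rows(spot_pool$rows, nvar),
                             spot_pool$rhs, spot_pool$labels)
    fams <- lapply(hc$families, pad_family, n = n, nvar = nvar)
    if (use_aux) {
      lin[nvar] <- 1
      if (ob$metric == "max_dose") {
        fams <- c(fams, list(aux_max_family(dij, vox, scen_idx, n, nvar, nvar,
                                            tol = tol)))
      } else {
        for (s in scen_idx) {
          r <- matrix(0, 1, nvar)
          r[, seq_len(n)] <- -mean_dose_row(dij, vox, s)
          r[, nvar] <- 1
          stage_pool <- pool_add(stage_pool, r, 0, "aux")
        }
      }
    } else {
      lin[seq_len(n)] <- mean_dose_row(dij, vox, 1L)
    }
    glab <- if (!is.null(groups)) c(groups, rep(NA_integer_, nvar - n)) else NULL
    res <- solve_penalized(nvar, lin, families = fams, pool = stage_pool,
                           groups = glab, lambda = lambda,
                           l1 = c(rep(l1, n), rep(0, nvar - n)),
                           ridge = ridge, tol = tol,
                           context = sprintf("priority %d (%s %s)", ob$priority,
                                             ob$structure, ob$metric))
    x <- res$x[seq_len(n)]
    achieved[k] <- metric_value(dij, phantom, ob$structure, ob$metric, x,
                                robust = ob$robust)
    # Carry forward: keep non-aux rows, then bound this objective.
    keep <- res$pool$labels != "aux"
    spot_pool <- new_pool(n)
    if (any(keep))
      spot_pool <- pool_add(spot_pool, res$pool$rows[keep, seq_len(n), drop = FALSE],
                            res$pool$rhs[keep], res$pool$labels[keep])
    bound <- if (ob$sufficient) max(achieved[k], ob$goal) * (1 + delta)
             else achieved[k] * (1 + delta)
    blab <- sprintf("priority %d bound", ob$priority)
    if (ob$metric == "mean_dose") {
      for (s in scen_idx)
        spot_pool <- pool_add(spot_pool, matrix(-mean_dose_row(dij, vox, s), 1),
                              -bound, blab)
    } else {
      hc$families <- c(hc$families,
                       list(dose_bound_family(dij, vox, scen_idx, bound, -1,
                                              blab, tol = tol)))
    }
  }
  new_plan(weights = stats::setNames(x, dij$spots$id), dij = dij, mode = mode,
           achieved = tibble::tibble(priority = obj$priority,
                                     structure = obj$structure,
                                     metric = obj$metric, goal = obj$goal,
                                     robust = obj$robust, achieved = achieved),
           wishlist = wishlist)
}

# --- scalarized surrogate ---------------------------------------------------

#' Solve the scalarized wish-list surrogate
#'
#' A weighted-sum surrogate of the prioritized objectives (priority k gets
#' weight `base^(1-k)`) under all hard constraints, optionally with an L1
#' spot penalty (SISS) or a group-lasso penalty over spot groups (energy
#' layers for ELR, beams for BAO). One convex solve; used by the
#' sparsification stages where a full lexicographic stack per candidate
#' coefficient would be intractable.
#'
#' @inheritParams solve_lexicographic
#' @param l1 L1 penalty coefficient (>= 0).
#' @param groups integer group label per (restricted) spot, for the group
#'   penalty.
#' @param lambda group-penalty coefficient (>= 0).
#' @param base priority weight base (default 10).
#' @return list with `weights` (named by spot id), `objective` (the
#'   surrogate objective value, penalty excluded, recomputed from the dose),
#'   `terms` (per-objective metric values), `group_norms` (when grouped).
#' @export
solve_surrogate <- function(dij, phantom, wishlist, support = NULL, l1 = 0,
                            groups = NULL, lambda = 0, base = 10,
                            ridge = 1e-7, tol = 1e-4,
                            spot_lower = 0, spot_upper = Inf) {
  wl_check_structures(wishlist, phantom)
  if (!is.null(support)) dij <- dij_subset(dij, support)
  n <- nrow(dij$spots)
  if (!n) stop_protonarc("empty spot support", "protonarc_spec_error")
  hc <- hard_constraint_set(dij, phantom, wishlist, tol = tol)
  obj <- wishlist$objectives
  wgt <- base^(1 - obj$priority)
  aux_for <- which(obj$metric == "max_dose" | (obj$metric == "mean_dose" & obj$robust))
  nvar <- n + length(aux_for)
  lin <- numeric(nvar)
  pool <- new_pool(nvar)
  if (nrow(hc$fixed$rows))
    pool <- pool_add(pool, pad_rows(hc$fixed$rows, nvar), hc$fixed$rhs,
                     hc$fixed$labels)
  fams <- lapply(hc$families, pad_family, n = n, nvar = nvar)
  for (k in seq_len(nrow(obj))) {
    ob <- obj[k, ]
    vox <- which(as.vector(phantom$masks[[ob$structure]]))
    scen_idx <- if (ob$robust) seq_len(nrow(dij$scenarios)) else 1L
    if (k %in% aux_for) {
      tcol <- n + match(k, aux_for)
      lin[tcol] <- wgt[k]
      if (ob$metric == "max_dose") {
        fams <- c(fams, list(aux_max_family(dij, vox, scen_idx, n, nvar, tcol,
                                            tol = tol)))
      } else {
        for (s in scen_idx) {
          r <- matrix(0, 1, nvar)
          r[, seq_len(n)] <- -mean_dose_row(dij, vox, s)
          r[, tcol] <- 1
          pool <- pool_add(pool, r, 0, "aux")
        }
      }
    } else {
      lin[seq_len(n)] <- lin[seq_len(n)] + wgt[k] * mean_dose_row(dij, vox, 1L)
    }
  }
  glab <- if (!is.null(groups)) c(groups, rep(NA_integer_, nvar - n)) else NULL
  res <- solve_penalized(nvar, lin, families = fams, pool = pool,
                         groups = glab, lambda = lambda,
                         l1 = c(rep(l1, n), rep(0, nvar - n)),
                         lower = c(rep_len(spot_lower, n), rep(0, nvar - n)),
                         upper = c(rep_len(spot_upper, n), rep(Inf, nvar - n)),
                         ridge = ridge, tol = tol, context = "surrogate solve")
  w <- res$x[seq_len(n)]
  terms <- vapply(seq_len(nrow(obj)), function(k)
    metric_value(dij, phantom, obj$structure[k], obj$metric[k], w,
                 robust = obj$robust[k]), numeric(1))
  out <- list(weights = stats::setNames(w, dij$spots$id),
              objective = sum(wgt * terms),
              terms = tibble::tibble(priority = obj$priority,
                                     structure = obj$structure,
                                     metric = obj$metric, value = terms,
                                     weight = wgt))
  if (!is.null(groups)) {
    if (!is.null(res$group_norms)) {
      out$group_norms <- tibble::tibble(group_id = seq_along(res$group_norms),
                                        norm2 = res$group_norms)
    } else {
      gn2 <- numeric(max(groups))
      agg <- tapply(w^2, groups, sum)
      gn2[as.integer(names(agg))] <- agg
      out$group_norms <- tibble::tibble(group_id = seq_along(gn2),
                                        norm2 = sqrt(gn2))
    }
  }
  out
}

#' Surrogate plan quality of a spot support
#'
#' Re-solves the unpenalized scalarized surrogate restricted to `support`
#' and returns its objective value — the plan-quality score used when
#' comparing energy-layer-reduced plans against the Utopia benchmark and
#' beam-angle configurations of increasing size.
#'
#' @inheritParams solve_surrogate
#' @return the surrogate objective value (smaller is better).
#' @export
surrogate_objective <- function(dij, phantom, wishlist, support = NULL,
                                base = 10, ridge = 1e-7, tol = 1e-4) {
  solve_surrogate(dij, phantom, wishlist, support = support, base = base,
                  ridge = ridge, tol = tol)$objective
}

# --- plans ------------------------------------------------------------------

new_plan <- function(weights, dij, mode, achieved, wishlist, extras = list()) {
  structure(c(list(
    weights = weights,
    spots = dij$spots,
    beams = dij$beams,
    mode = mode,
    achieved = achieved,
    wishlist_digest = wishlist_digest(wishlist),
    selected_els = dplyr::distinct(dij$spots[weights > 1e-9, ],
                                   field_index, el_index)
  ), extras), class = "protonarc_plan")
}

#' @exportS3Method base::print
print.protonarc_plan <- function(x, ...) {
  cat(sprintf("<protonarc_plan> mode %s: %d fields, %d spots (%d active), %d ELs\n",
              x$mode, nrow(x$beams), length(x$weights),
              sum(x$weights > 1e-9), nrow(x$selected_els)))
  if (!is.null(x$achieved)) print(as.data.frame(x$achieved))
  invisible(x)
}

# Weights of a plan aligned to the columns of a dij (missing spots get 0).
plan_weights_for <- function(plan, dij) {
  w <- numeric(nrow(dij$spots))
  m <- match(names(plan$weights), as.character(dij$spots$id))
  ok <- !is.na(m)
  w[m[ok]] <- plan$weights[ok]
  w
}

#' Maximum single-field dose contribution of a plan
#'
#' The largest dose any voxel receives from one field's spots alone, in the
#' nominal scenario — the quantity capped at 47 Gy during optimization.
#'
#' @param plan a `protonarc_plan`.
#' @param dij the dose-influence set the plan was optimized on.
#' @param field field index.
#' @return max per-field voxel dose (Gy_RBE).
#' @export
per_field_max_dose <- function(plan, dij, field) {
  if (!field %in% dij$beams$field_index)
    stop_protonarc(sprintf("unknown field %s", field), "protonarc_spec_error")
  w <- plan_weights_for(plan, dij)
  cols <- which(dij$spots$field_index == field)
  if (!length(cols)) return(0)
  max(0, as.vector(dij$matrices[[1]][, cols, drop = FALSE] %*% w[cols]))
}

#' Tidy a plan's achieved objective table
#'
#' @param x a `protonarc_plan`.
#' @param ... unused.
#' @return tibble with one row per wish-list priority.
#' @exportS3Method generics::tidy
tidy.protonarc_plan <- function(x, ...) x$achieved

#' One-row summary of a plan
#'
#' @param x a `protonarc_plan`.
#' @param ... unused.
#' @return tibble with mode, counts and total MU.
#' @exportS3Method generics::glance
glance.protonarc_plan <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_fields = nrow(x$beams),
                 n_spots = sum(x$weights > 1e-9),
                 n_els = nrow(x$selected_els),
                 total_mu = sum(x$weights))
}
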