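# Convex solver core shared by MCO, SISS, ELR and BAO.
#
# Every stage is a linear cost (plus optional L1 / group-lasso penalties)
# under linear inequality constraints and nonnegativity. Stages are solved
# as strictly convex QPs (quadprog) with a small Tikhonov ridge: as the
# ridge goes to zero this selects the minimum-norm optimum of the
# underlying LP, which doubles as the documented tie-break among equal-cost
# optima. Voxel-wise constraint families (robust min/max dose, per-field
# caps, max-dose auxiliary bounds) are handled by cutting planes: solve,
# find the worst violated voxel rows, add them, repeat. Group-lasso
# penalties are handled by an MM scheme (iteratively reweighted quadratic
# majorization of the smoothed group norm) around the same QP core.

new_pool <- function(nvar) {
  list(rows = matrix(0, 0, nvar), rhs = numeric(0), labels = character(0))
}

pool_add <- function(pool, rows, rhs, labels) {
  pool$rows <- rbind(pool$rows, rows)
  pool$rhs <- c(pool$rhs, rhs)
  pool$labels <- c(pool$labels, labels)
  pool
}

# Solve min lin.x + 0.5 x' diag(ridge + hdiag) x  s.t. pool rows A x >= b,
# lower <= x <= upper, expanding the pool from the constraint families until
# no family member is violated by more than tol.
#
# families: list of list(label=, fn=function(x) list(rows, rhs)) returning
# the (worst) violated rows in A x >= b form.
cp_solve <- function(nvar, lin, hdiag = NULL, pool = NULL, families = list(),
                     lower = rep(0, nvar), upper = rep(Inf, nvar),
                     ridge = 1e-7, tol = 1e-4, max_iter = 100) {
  if (is.null(pool)) pool <- new_pool(nvar)
  if (is.null(hdiag)) hdiag <- numeric(nvar)
  bound_rows <- NULL
  bound_rhs <- NULL
  ilo <- which(is.finite(lower))
  if (length(ilo)) {
    m <- matrix(0, length(ilo), nvar); m[cbind(seq_along(ilo), ilo)] <- 1
    bound_rows <- m; bound_rhs <- lower[ilo]
  }
  iup <- which(is.finite(upper))
  if (length(iup)) {
    m <- matrix(0, length(iup), nvar); m[cbind(seq_along(iup), iup)] <- -1
    bound_rows <- rbind(bound_rows, m); bound_rhs <- c(bound_rhs, -upper[iup])
  }
  x <- NULL
  for (it in seq_len(max_iter)) {
    A <- rbind(bound_rows, pool$rows)
    b <- c(bound_rhs, pool$rhs)
    Dmat <- diag(ridge + hdiag, nvar)
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, -lin, t(A), b, meq = 0),
      error = function(e) e)
    if (inherits(sol, "error")) {
      if (grepl("inconsistent", conditionMessage(sol)))
        return(list(x = x, pool = pool, status = "infeasible"))
      stop_protonarc(sprintf("QP stage failed: %s", conditionMessage(sol)),
                     "protonarc_solver_error")
    }
    x <- sol$solution
    added <- FALSE
    for (fam in families) {
      v <- fam$fn(x)
      if (!is.null(v) && nrow(v$rows)) {
        pool <- pool_add(pool, v$rows, v$rhs, rep(fam$label, nrow(v$rows)))
        added <- TRUE
      }
    }
    if (!added) return(list(x = x, pool = pool, status = "optimal", iterations = it))
  }
  stop_protonarc("cutting-plane loop did not converge", "protonarc_solver_error")
}

# Elastic re-solve of an infeasible pool: one slack per constraint label,
# minimize total slack; used to name the violated constraints.
diagnose_infeasible <- function(nvar, pool, lower, upper, ridge = 1e-7) {
  labs <- unique(pool$labels)
  ns <- length(labs)
  n <- nvar + ns
  A <- cbind(pool$rows, matrix(0, nrow(pool$rows), ns))
  for (k in seq_len(ns))
    A[pool$labels == labs[k], nvar + k] <- 1
  lo <- c(lower, rep(0, ns))
  up <- c(upper, rep(Inf, ns))
  lin <- c(numeric(nvar), rep(1, ns))
  res <- cp_solve(n, lin, pool = {
    p <- new_pool(n); pool_add(p, A, pool$rhs, pool$labels)
  }, lower = lo, upper = up, ridge = ridge)
  slack <- res$x[nvar + seq_len(ns)]
  tibble::tibble(constraint = labs, slack_gy = slack)[slack > 1e-3, ]
}

report_infeasible <- function(nvar, pool, lower, upper, context) {
  diag_ <- tryCatch(diagnose_infeasible(nvar, pool, lower, upper),
                    error = function(e) NULL)
  first <- if (!is.null(diag_) && nrow(diag_)) diag_$constraint[1] else "unknown"
  stop_protonarc(
    sprintf("%s: hard constraints infeasible (first violated: %s)", context, first),
    "protonarc_infeasible", violated = diag_)
}

# Group-lasso penalized solve: min lin.x + l1*sum(x) +
# lambda * sum_g sqrt(|g|) ||x_g||_2 under the same constraint machinery.
# `groups` is an integer vector (length nvar) of group memberships.
solve_penalized <- function(nvar, lin, families = list(), pool = NULL,
                            groups = NULL, lambda = 0, l1 = 0,
                            lower = rep(0, nvar), upper = rep(Inf, nvar),
                            ridge = 1e-7, tol = 1e-4, mm_iter = 30,
                            context = "penalized solve") {
  lin2 <- lin + l1
  res <- cp_solve(nvar, lin2, pool = pool, families = families,
                  lower = lower, upper = upper, ridge = ridge, tol = tol)
  if (res$status == "infeasible")
    report_infeasible(nvar, res$pool, lower, upper, context)
  if (is.null(groups) || lambda <= 0) return(res)
  pen <- !is.na(groups)
  gidx <- groups[pen]
  gsize <- tabulate(gidx)
  scale <- max(abs(res$x), 1e-6)
  eps_min <- 1e-4 * scale
  x <- res$x
  pool <- res$pool
  # Annealed smoothing: the IRLS majorizer of ||x_g|| freezes groups that
  # sit exactly at zero when eps is tiny, so eps starts at the solution
  # scale and halves per iteration down to eps_min before the convergence
  # test applies.
  gn_hist <- list()
  group_norm <- function(xx) {
    gn2 <- numeric(length(gsize))
    agg <- tapply(xx[pen]^2, gidx, sum)
    gn2[as.integer(names(agg))] <- agg
    sqrt(gn2)
  }
  for (it in seq_len(mm_iter)) {
    eps <- max(eps_min, scale * 0.5^(it - 1))
    r <- sqrt(group_norm(x)^2 + eps^2)
    hdiag <- numeric(nvar)
    hdiag[pen] <- lambda * sqrt(gsize)[gidx] / r[gidx]
    res <- cp_solve(nvar, lin2, hdiag = hdiag, pool = pool, families = families,
                    lower = lower, upper = upper, ridge = ridge, tol = tol)
    if (res$status == "infeasible")
      report_infeasible(nvar, res$pool, lower, upper, context)
    pool <- res$pool
    converged <- max(abs(res$x - x)) < 1e-4 * scale && eps <= eps_min
    x <- res$x
    gn_hist[[length(gn_hist) + 1L]] <- group_norm(x)
    if (converged) break
  }
  res$x <- x
  # The IRLS tail is geometric: norms of dying groups shrink by a constant
  # factor per iteration. Aitken delta-squared extrapolation of the last
  # three group-norm vectors recovers the limits, giving a crisp selection
  # without running the tail out. Only the selection uses these; downstream
  # stages re-solve on the selected support.
  k <- length(gn_hist)
  gn_inf <- gn_hist[[k]]
  if (k >= 3) {
    d2 <- gn_hist[[k]] - gn_hist[[k - 1]]
    d1 <- gn_hist[[k - 1]] - gn_hist[[k - 2]]
    den <- d2 - d1
    ok <- abs(den) > 1e-12 & abs(d2) < abs(d1)  # geometric decay/growth only
    gn_inf[ok] <- pmax(0, gn_hist[[k]][ok] - d2[ok]^2 / den[ok])
  }
  res$group_norms <- gn_inf
  res
}
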