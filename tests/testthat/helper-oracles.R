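# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's solver/engine code paths: tiny LPs are solved by
# vertex enumeration, doses by dense ray sampling, test statistics by
# exhaustive sign-flip enumeration.

# Exact solver for min c'w s.t. A w >= b, w >= 0 by enumerating basic
# feasible points (all choices of n active constraints among rows and
# bounds). Only for tiny n.
oracle_lp_vertex <- function(cvec, A, b) {
  n <- length(cvec)
  rows <- rbind(A, diag(n))        # bound rows w_i >= 0
  rhs <- c(b, numeric(n))
  m <- nrow(rows)
  best <- NULL; best_w <- NULL
  for (act in utils::combn(m, n, simplify = FALSE)) {
    M <- rows[act, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    w <- tryCatch(solve(M, rhs[act]), error = function(e) NULL)
    if (is.null(w)) next
    if (any(w < -1e-8)) next
    if (any(rows %*% w < rhs - 1e-6)) next
    val <- sum(cvec * w)
    if (is.null(best) || val < best - 1e-12) { best <- val; best_w <- w }
  }
  list(value = best, w = best_w)
}

# Dense independent ray-trace: does the segment from far upstream to the
# Bragg-peak position of a spot cross a blocking mask?
oracle_spot_blocked <- function(phantom, spot, beam, mask, step = 0.5) {
  ax <- protonarc:::beam_axes(beam$gantry_deg, beam$couch_deg)
  q <- phantom$isocenter_mm + spot$lat1_mm * ax$l1 + spot$lat2_mm * ax$l2
  tmax <- sqrt(sum((phantom$grid$shape * phantom$grid$spacing_mm)^2)) + 5
  ts <- seq(-tmax, tmax, by = step)
  dens <- as.vector(phantom$density)
  wet <- 0
  for (t in ts) {
    p <- q + t * ax$d
    idx <- protonarc:::world_to_voxel(phantom$grid, matrix(p, 1))
    d_here <- if (is.na(idx)) 0 else dens[idx]
    wet <- wet + d_here * step
    if (!is.na(idx) && as.vector(mask)[idx]) return(TRUE)
    if (wet >= spot$peak_wet_mm) return(FALSE)
  }
  FALSE
}

# Exhaustive sign-flip enumeration of the Wilcoxon signed-rank two-sided
# p-value (zeros dropped, mid-ranks), for n <= 12.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- sum(r)
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Sort-and-scan DVH percentile: largest dose level d such that at least
# q% of the voxels receive >= d (scan over the observed dose levels).
oracle_dq <- function(doses, q) {
  lev <- sort(unique(doses), decreasing = TRUE)
  frac <- vapply(lev, function(l) mean(doses >= l), numeric(1))
  max(lev[frac >= q / 100])
}

# Radiological depth by closed-form line integral for piecewise-constant
# density slabs along -y (the slab_phantom geometry).
oracle_slab_wet <- function(depth_mm, density) depth_mm * density
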