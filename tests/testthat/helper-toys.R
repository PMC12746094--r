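# Small constructed optimization beds shared across test files.

# 5-spot / 4-voxel sparsification bed: two target voxels under a min-dose
# constraint and a mean-dose cost over two OAR voxels; supports shrink as
# the L1 coefficient grows.
siss_toy <- function() {
  Dt <- rbind(c(1.0, 0.1, 0.6, 0.5, 0.05),
              c(0.1, 1.0, 0.6, 0.05, 0.5))
  Do <- rbind(c(0.20, 0.20, 0.05, 0.01, 0.01),
              c(0.20, 0.20, 0.05, 0.01, 0.01))
  D <- rbind(Dt, Do)
  phantom <- protonarc:::toy_phantom(4, list(target = c(TRUE, TRUE, FALSE, FALSE),
                                             oar = c(FALSE, FALSE, TRUE, TRUE)),
                                     c(target = "target_high", oar = "oar_parallel"))
  wl <- parse_wishlist(list(
    constraints = data.frame(structure = "target", metric = "min_dose",
                             bound = 60, robust = FALSE),
    objectives = data.frame(priority = 1L, structure = "oar",
                            metric = "mean_dose", goal = 1,
                            sufficient = FALSE, robust = FALSE)))
  list(dij = protonarc:::toy_dij(D), phantom = phantom, wishlist = wl,
       Dt = Dt, cost = colMeans(Do))
}

# Energy-layer reduction bed: three single-spot layers each covering one
# target voxel cheaply, plus one broad three-spot layer that can cover all
# three voxels alone at a slightly higher OAR cost. Group regularization
# must switch from the three narrow layers to the single broad one as the
# coefficient grows.
elr_toy <- function() {
  Dt <- cbind(diag(3), 1.2 * diag(3))
  Do <- matrix(c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02), 1)
  D <- rbind(Dt, Do)
  el <- c(1L, 2L, 3L, 4L, 4L, 4L)
  phantom <- protonarc:::toy_phantom(4, list(target = c(rep(TRUE, 3), FALSE),
                                             oar = c(rep(FALSE, 3), TRUE)),
                                     c(target = "target_high", oar = "oar_parallel"))
  wl <- parse_wishlist(list(
    constraints = data.frame(structure = "target", metric = "min_dose",
                             bound = 60, robust = FALSE),
    objectives = data.frame(priority = 1L, structure = "oar",
                            metric = "mean_dose", goal = 0.5,
                            sufficient = FALSE, robust = FALSE)))
  list(dij = protonarc:::toy_dij(D, el_index = el), phantom = phantom,
       wishlist = wl)
}
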