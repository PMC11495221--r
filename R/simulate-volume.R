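#' Specification for synthetic grey-matter volumes
#'
#' Synthetic volumes stand in for real grey-matter segmentations: the cube
#' grid is partitioned into `n_communities` groups, and all cubes of a
#' community share a latent intensity pattern whose amplitude relative to the
#' voxel noise controls the intraclass correlation of within-community cube
#' pairs: `icc = s^2 / (s^2 + 1)` with `s = community_signal` (the sd ratio
#' of shared signal to noise).
#'
#' @param shape Integer length-3, voxels per axis.
#' @param n_communities Number of cube communities.
#' @param community_signal Signal-to-noise sd ratio (>= 0); 0 gives pure
#'   noise volumes.
#' @param noise_sd Voxel noise sd on the probability scale (keep small so
#'   clipping to `[0, 1]` stays negligible).
#' @param gm_baseline Baseline grey-matter probability.
#' @param cube_edge Cube edge (matching the downstream parcellation).
#' @param seed Integer seed.
#' @return A `volume_sim_spec` list.
#' @export
volume_sim_spec <- function(shape = c(30, 30, 30), n_communities = 12,
                            community_signal = 3, noise_sd = 0.05,
                            gm_baseline = 0.5, cube_edge = 3L, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 2 * cube_edge),
            n_communities >= 1, community_signal >= 0, noise_sd > 0,
            gm_baseline >= 0, gm_baseline <= 1)
  structure(list(shape = as.integer(shape), n_communities = as.integer(n_communities),
                 community_signal = community_signal, noise_sd = noise_sd,
                 gm_baseline = gm_baseline, cube_edge = as.integer(cube_edge),
                 seed = as.integer(seed)),
            class = "volume_sim_spec")
}

#' Simulate a grey-matter volume with community covariance structure
#'
#' Each voxel value is `clip(gm_baseline + s * noise_sd * L_c[pos] +
#' noise_sd * eps, 0, 1)` where `L_c` is a community-specific latent pattern
#' over the within-cube voxel positions (shared by every cube of community
#' `c`, independent across communities), `pos` is the voxel's position within
#' its cube, and `eps` is iid standard normal voxel noise. Cube pairs in the
#' same community therefore have expected Pearson correlation
#' `s^2 / (s^2 + 1)`; pairs across communities are uncorrelated. The
#' community assignment of every cube is returned as ground truth.
#'
#' @param spec A [volume_sim_spec()].
#' @param seed Optional seed override.
#' @return A [gm_volume] with attribute `ground_truth` (community label per
#'   cube in parcellation node order).
#' @export
simulate_volume <- function(spec = volume_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "volume_sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  e <- spec$cube_edge
  dims <- spec$shape
  nb <- dims %/% e
  n_cubes <- prod(nb)
  # community partition of the cube grid (every cube in exactly one community)
  community <- sample(rep_len(seq_len(spec$n_communities), n_cubes))
  # latent within-cube pattern per community
  L <- matrix(stats::rnorm(spec$n_communities * e^3), spec$n_communities, e^3)

  vals <- array(spec$gm_baseline + spec$noise_sd * stats::rnorm(prod(dims)), dim = dims)
  # add the shared community signal cube by cube, in parcellation node order
  g <- expand.grid(oz = seq(0L, by = e, length.out = nb[3]),
                   oy = seq(0L, by = e, length.out = nb[2]),
                   ox = seq(0L, by = e, length.out = nb[1]),
                   KEEP.OUT.ATTRS = FALSE)[, 3:1]
  g <- g[order(g$ox, g$oy, g$oz), , drop = FALSE]
  off <- expand.grid(dx = 0:(e - 1), dy = 0:(e - 1), dz = 0:(e - 1),
                     KEEP.OUT.ATTRS = FALSE)
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  dlin <- off$dx + off$dy * nx + off$dz * nxy
  base_lin <- 1 + g$ox + g$oy * nx + g$oz * nxy
  amp <- spec$community_signal * spec$noise_sd
  for (i in seq_len(n_cubes)) {
    vals[base_lin[i] + dlin] <- vals[base_lin[i] + dlin] + amp * L[community[i], ]
  }
  vals <- pmin(pmax(vals, 0), 1)
  vol <- gm_volume(vals, spacing = c(2, 2, 2))
  attr(vol, "ground_truth") <- list(community = community,
                                    icc = spec$community_signal^2 /
                                          (spec$community_signal^2 + 1))
  vol
}

#' Simulate a null volume with no spatial structure
#'
#' Voxel values are iid uniform on `[gm_baseline - half_width, gm_baseline +
#' half_width]`: no cube pair carries shared signal, so all cube-pair
#' correlations are chance-level. Used to calibrate the permutation
#' threshold.
#'
#' @param shape Integer length-3, voxels per axis.
#' @param seed Integer seed.
#' @param gm_baseline Centre of the value distribution.
#' @param half_width Half-range of the uniform distribution.
#' @return A [gm_volume].
#' @export
simulate_null_volume <- function(shape = c(30, 30, 30), seed = 1L,
                                 gm_baseline = 0.5, half_width = 0.3) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            gm_baseline - half_width >= 0, gm_baseline + half_width <= 1)
  set.seed(seed)
  vals <- array(stats::runif(prod(shape), gm_baseline - half_width,
                             gm_baseline + half_width), dim = shape)
  gm_volume(vals, spacing = c(2, 2, 2))
}
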