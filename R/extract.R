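#' Parcellate a grey-matter volume into cubic nodes
#'
#' Tiles the volume with axis-aligned cubes of `cube_edge^3` voxels starting
#' at voxel (0,0,0); trailing partial slabs are discarded. A cube becomes an
#' included network node when at least `min_gm_voxels` of its voxels exceed
#' `gm_threshold` grey-matter probability. Node order is lexicographic by
#' cube origin (first axis slowest), so parcellation is deterministic.
#'
#' @param vol A [gm_volume].
#' @param cube_edge Cube edge in voxels (default 3, i.e. 27 voxels per node).
#' @param gm_threshold Probability above which a voxel counts as grey matter.
#' @param min_gm_voxels Minimum grey voxels for cube inclusion.
#' @return An object of class `cube_parcellation`: 0-based cube origins,
#'   an `n x cube_edge^3` intensity matrix in fixed within-cube scan order,
#'   and the inclusion mask.
#' @export
parcellate <- function(vol, cube_edge = 3L, gm_threshold = 0.1, min_gm_voxels = 1L) {
  stopifnot(inherits(vol, "gm_volume"))
  dims <- dim(vol$values)
  cube_edge <- as.integer(cube_edge)
  if (any(dims < cube_edge)) stop("volume smaller than one cube along some axis")
  nb <- dims %/% cube_edge
  nx <- dims[1]; nxy <- dims[1] * dims[2]

  ax <- lapply(nb, function(m) seq(0L, by = cube_edge, length.out = m))
  # lexicographic by origin: first axis varies slowest
  g <- expand.grid(oz = ax[[3]], oy = ax[[2]], ox = ax[[1]],
                   KEEP.OUT.ATTRS = FALSE)[, 3:1]
  g <- g[order(g$ox, g$oy, g$oz), , drop = FALSE]
  origins <- as.matrix(g)
  rownames(origins) <- NULL

  off <- expand.grid(dx = 0:(cube_edge - 1), dy = 0:(cube_edge - 1),
                     dz = 0:(cube_edge - 1), KEEP.OUT.ATTRS = FALSE)
  dlin <- off$dx + off$dy * nx + off$dz * nxy
  base_lin <- 1 + origins[, 1] + origins[, 2] * nx + origins[, 3] * nxy
  idx <- outer(base_lin, dlin, "+")
  intens <- matrix(vol$values[idx], nrow = nrow(origins))

  included <- rowSums(intens > gm_threshold) >= min_gm_voxels
  structure(list(origins = origins,
                 intensities = intens,
                 included = included,
                 cube_edge = cube_edge,
                 gm_threshold = gm_threshold,
                 min_gm_voxels = as.integer(min_gm_voxels),
                 volume_dim = dims),
            class = "cube_parcellation")
}

#' @export
print.cube_parcellation <- function(x, ...) {
  cat(sprintf("cube_parcellation: %d cubes (%d included) of edge %d\n",
              nrow(x$origins), sum(x$included), x$cube_edge))
  invisible(x)
}

# index permutations of the cube scan order under the 48 axis-aligned
# rotations/reflections of a cube grid (axis permutation x axis reversal)
cube_rotation_perms <- function(cube_edge) {
  e <- cube_edge
  coords <- as.matrix(expand.grid(0:(e - 1), 0:(e - 1), 0:(e - 1)))
  axperms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  perms <- vector("list", 48)
  k <- 0
  for (p in seq_len(nrow(axperms))) {
    for (s in seq_len(nrow(signs))) {
      k <- k + 1
      nc <- coords[, axperms[p, ], drop = FALSE]
      for (a in 1:3) if (signs[s, a] < 0) nc[, a] <- (e - 1) - nc[, a]
      perms[[k]] <- 1 + nc[, 1] + nc[, 2] * e + nc[, 3] * e * e
    }
  }
  perms
}

#' Pairwise Pearson correlation between cube intensity vectors
#'
#' Computes the Pearson correlation of grey-matter intensities across voxels
#' for every pair of included cubes. In rotation mode the correlation of a
#' pair is the maximum over the 48 axis-aligned rotations/reflections of the
#' second cube's intensity grid (compatibility with the original network
#' extraction code); the default is the plain pairwise correlation. Cubes
#' with zero intensity variance yield flagged undefined (`NA`) entries.
#'
#' @param parc A [cube_parcellation].
#' @param rotation_mode Maximize correlations over cube rotations?
#' @return An object of class `correlation_matrix`: the symmetric `r` matrix
#'   with `NA` diagonal, node origins, and the undefined-node flag.
#' @export
correlate <- function(parc, rotation_mode = FALSE) {
  stopifnot(inherits(parc, "cube_parcellation"))
  keep <- which(parc$included)
  if (length(keep) < 2) stop("need at least 2 included nodes to correlate")
  X <- t(parc$intensities[keep, , drop = FALSE])  # voxels x nodes
  m <- ncol(X); nv <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ss <- sqrt(colSums(Xc^2))
  degenerate <- ss == 0
  ssafe <- ifelse(degenerate, 1, ss)
  Z <- sweep(Xc, 2, ssafe, "/")
  if (!rotation_mode) {
    R <- crossprod(Z)
  } else {
    perms <- cube_rotation_perms(parc$cube_edge)
    R <- matrix(-Inf, m, m)
    for (p in perms) R <- pmax(R, crossprod(Z, Z[p, , drop = FALSE]))
    R <- pmax(R, t(R))  # rotating either cube of the pair
  }
  R[degenerate, ] <- NA_real_
  R[, degenerate] <- NA_real_
  R <- pmin(pmax(R, -1), 1)
  diag(R) <- NA_real_
  structure(list(r = R,
                 origins = parc$origins[keep, , drop = FALSE],
                 undefined = degenerate,
                 rotation_mode = rotation_mode),
            class = "correlation_matrix")
}

#' Subject-specific permutation threshold for network binarization
#'
#' Destroys the spatial structure of the volume by shuffling in-mask voxel
#' values across in-mask positions (the value distribution is untouched),
#' re-parcellates the permuted volume, and computes the null distribution of
#' cube-pair correlations. The returned threshold is the `1 - alpha` upper
#' quantile of that null, so applying it to the subject's real correlation
#' matrix admits only the fraction `alpha` of chance-level correlations.
#'
#' @param vol A [gm_volume].
#' @param cube_edge,gm_threshold,min_gm_voxels Parcellation parameters, as in
#'   [parcellate()].
#' @param alpha Upper-tail fraction of the null to retain (default 0.05).
#' @param n_null_pairs Maximum node pairs sampled from the null.
#' @param seed Integer seed for the shuffle and pair subsampling.
#' @param rotation_mode Passed to [correlate()].
#' @return Numeric threshold with attributes `n_null_nodes`, `n_null_pairs`.
#' @export
permutation_threshold <- function(vol, cube_edge = 3L, gm_threshold = 0.1,
                                  min_gm_voxels = 1L, alpha = 0.05,
                                  n_null_pairs = 1e6, seed = 1L,
                                  rotation_mode = FALSE) {
  stopifnot(inherits(vol, "gm_volume"), alpha > 0, alpha < 1)
  set.seed(seed)
  vals <- vol$values
  mask <- which(vals > gm_threshold)
  if (length(mask) < 2 * cube_edge^3) stop("too few in-mask voxels to permute")
  perm <- vals
  perm[mask] <- vals[mask][sample.int(length(mask))]
  pvol <- gm_volume(perm, spacing = vol$spacing)
  parc <- parcellate(pvol, cube_edge, gm_threshold, min_gm_voxels)
  if (sum(parc$included) < 2) stop("degenerate permuted volume: fewer than 2 nodes")
  cm <- correlate(parc, rotation_mode = rotation_mode)
  null_r <- cm$r[upper.tri(cm$r)]
  null_r <- null_r[is.finite(null_r)]
  if (length(null_r) > n_null_pairs) {
    null_r <- null_r[sample.int(length(null_r), n_null_pairs)]
  }
  thr <- stats::quantile(null_r, probs = 1 - alpha, names = FALSE, type = 7)
  attr(thr, "n_null_nodes") <- sum(parc$included)
  attr(thr, "n_null_pairs") <- length(null_r)
  thr
}

#' Binarize a correlation matrix at a threshold
#'
#' Edges connect node pairs with correlation strictly above the threshold;
#' only positive supra-threshold correlations can form edges (the null
#' quantile construction is one-sided, upper tail). Undefined correlations
#' never form edges.
#'
#' @param corr A `correlation_matrix` from [correlate()].
#' @param threshold Finite correlation threshold.
#' @return A [binary_network].
#' @export
binarize <- function(corr, threshold) {
  stopifnot(inherits(corr, "correlation_matrix"), is.finite(threshold))
  A <- corr$r > as.numeric(threshold)
  A[is.na(A)] <- FALSE
  diag(A) <- FALSE
  binary_network(A, origins = corr$origins, threshold = as.numeric(threshold))
}

#' Extract a single-subject network from a grey-matter volume
#'
#' Convenience wrapper running parcellation, pairwise correlation,
#' permutation thresholding and binarization with one configuration.
#'
#' @param vol A [gm_volume].
#' @param config An [analysis_config()].
#' @param seed Seed for the permutation null (defaults to the config seed).
#' @return A [binary_network].
#' @export
extract_network <- function(vol, config = analysis_config(), seed = NULL) {
  if (is.null(seed)) seed <- split_seed(config$seed, "permutation_threshold")
  parc <- parcellate(vol, config$cube_edge, config$gm_inclusion_threshold,
                     config$min_gm_voxels)
  cm <- correlate(parc, rotation_mode = config$rotation_mode)
  thr <- permutation_threshold(vol,
                               cube_edge = config$cube_edge,
                               gm_threshold = config$gm_inclusion_threshold,
                               min_gm_voxels = config$min_gm_voxels,
                               alpha = config$null_alpha,
                               n_null_pairs = config$n_null_pairs,
                               seed = seed,
                               rotation_mode = config$rotation_mode)
  binarize(cm, thr)
}
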