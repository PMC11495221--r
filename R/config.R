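#' Analysis configuration
#'
#' Bundles the fixed method constants of the pipeline: the cube edge used for
#' parcellation (3 voxels), the upper-tail fraction of the permutation null
#' used for thresholding (0.05), the number of degree-preserving random
#' reference graphs for the small-world coefficient (5), and the MCMC and
#' EYO-grid settings for the trajectory models.
#'
#' @param cube_edge Edge of the cubic parcels, in voxels.
#' @param gm_inclusion_threshold Grey-matter probability above which a voxel
#'   counts towards cube inclusion.
#' @param min_gm_voxels Minimum number of voxels above
#'   `gm_inclusion_threshold` for a cube to become a network node.
#' @param null_alpha Upper-tail fraction of the permutation null retained as
#'   significant; the binarization threshold is the `1 - null_alpha` quantile
#'   of the null correlation distribution.
#' @param n_null_pairs Maximum number of node pairs sampled from the permuted
#'   volume when building the null distribution.
#' @param n_random_graphs Number of degree-preserving randomizations used to
#'   normalize clustering and path length.
#' @param rotation_mode If `TRUE`, pairwise cube correlations are maximized
#'   over the 48 axis-aligned rotations/reflections of the second cube.
#' @param mcmc_chains,mcmc_iter,mcmc_thin MCMC settings for trajectory fits;
#'   the first half of `mcmc_iter` is treated as warmup.
#' @param eyo_grid Numeric vector `c(min, max, step)` in years defining the
#'   grid on which trajectory difference curves are evaluated.
#' @param seed Integer master seed; all stage seeds are derived from it.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(cube_edge = 3L,
                            gm_inclusion_threshold = 0.1,
                            min_gm_voxels = 1L,
                            null_alpha = 0.05,
                            n_null_pairs = 1e6,
                            n_random_graphs = 5L,
                            rotation_mode = FALSE,
                            mcmc_chains = 8L,
                            mcmc_iter = 10000L,
                            mcmc_thin = 10L,
                            eyo_grid = c(-25, 10, 0.5),
                            seed = 1L) {
  stopifnot(cube_edge >= 1, null_alpha > 0, null_alpha < 1,
            n_null_pairs > 0, n_random_graphs > 0,
            mcmc_chains > 0, mcmc_iter > 0, mcmc_thin > 0,
            length(eyo_grid) == 3, eyo_grid[3] > 0, eyo_grid[1] < eyo_grid[2],
            gm_inclusion_threshold >= 0, gm_inclusion_threshold <= 1)
  cfg <- list(
    cube_edge = as.integer(cube_edge),
    gm_inclusion_threshold = gm_inclusion_threshold,
    min_gm_voxels = as.integer(min_gm_voxels),
    null_alpha = null_alpha,
    n_null_pairs = as.integer(n_null_pairs),
    n_random_graphs = as.integer(n_random_graphs),
    rotation_mode = isTRUE(rotation_mode),
    mcmc_chains = as.integer(mcmc_chains),
    mcmc_iter = as.integer(mcmc_iter),
    mcmc_thin = as.integer(mcmc_thin),
    eyo_grid = as.numeric(eyo_grid),
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Write / read a configuration as flat key = value text
#'
#' The on-disk format is one `key = value` line per field (vectors
#' comma-separated), human-diffable and lossless.
#'
#' @param config An `analysis_config` object.
#' @param path File path.
#' @return `read_config` returns an `analysis_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE), collapse = ", ")
  }
  lines <- vapply(names(config), function(k) paste(k, "=", fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*)$", lines))
  vals <- list()
  for (m in kv) {
    stopifnot(length(m) == 3)
    key <- m[2]
    raw <- trimws(strsplit(m[3], ",")[[1]])
    vals[[key]] <- if (all(raw %in% c("true", "false"))) raw == "true" else as.numeric(raw)
  }
  do.call(analysis_config, vals)
}

#' Derive per-stage seeds from a master seed
#'
#' All randomness in the pipeline flows from one top-level seed that is split
#' deterministically per named stage, so any stage can be re-run in isolation
#' and reproduce its output.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label, or an integer index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stage) {
  idx <- if (is.character(stage)) {
    # stable small hash of the stage label
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.integer(stage)
  }
  s <- (as.numeric(seed) %% 2147483647) + 1
  # two rounds of a Lehmer-style mix keep stage streams well separated
  s <- (s * 48271 + idx * 16807) %% 2147483647
  s <- (s * 69621 + 12345) %% 2147483647
  as.integer(s + 1)
}
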