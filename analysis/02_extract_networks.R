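#!/usr/bin/env Rscript
# Extract single-subject covariance networks from the simulated volumes and
# compute their small-world statistics against degree-preserving references.
# Usage: Rscript analysis/02_extract_networks.R [--seed <int>]

suppressMessages(library(gmnet))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[which(args == "--seed") + 1] else 1)
dir.create("results/networks", recursive = TRUE, showWarnings = FALSE)

for (name in c("structured", "null")) {
  vol <- read_gm_volume(sprintf("results/volumes/%s.nii.gz", name))
  cfg <- analysis_config(seed = split_seed(seed, name))
  parc <- parcellate(vol, cfg$cube_edge, cfg$gm_inclusion_threshold,
                     cfg$min_gm_voxels)
  thr <- permutation_threshold(vol, alpha = cfg$null_alpha,
                               n_null_pairs = cfg$n_null_pairs,
                               seed = split_seed(seed, paste0(name, "_thr")))
  net <- binarize(correlate(parc), thr)
  write_network(net, sprintf("results/networks/%s", name))
  m <- small_world(net, n_random = cfg$n_random_graphs,
                   seed = split_seed(seed, paste0(name, "_sw")))
  jsonlite::write_json(unclass(m), sprintf("results/networks/%s_metrics.json", name),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf(paste0("%s: %d nodes, %d edges (threshold %.3f, density %.3f); ",
                     "C=%.3f L=%.3f gamma=%.2f lambda=%.2f sigma=%.2f\n"),
              name, net$n_nodes, net$n_edges, net$threshold,
              net$n_edges / choose(net$n_nodes, 2),
              m$clustering, m$path_length, m$gamma, m$lambda, m$sigma))
}
cat("note: both networks show sigma > 1 because thresholded correlation graphs\n")
cat("are transitive by construction; the structured volume exceeds its own\n")
cat("chance level through community covariance.\n")
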