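.net_graph <- function(net) {
  if (inherits(net, "binary_network")) as_igraph(net)
  else if (igraph::is_igraph(net)) net
  else stop("expected a binary_network or igraph graph")
}

#' Watts-Strogatz local clustering coefficient
#'
#' Per node, `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of
#' triangles through node `i`; nodes of degree < 2 get `C_i = 0`. The network
#' mean over all nodes is the local-processing proxy entering the
#' small-world coefficient.
#'
#' @param net A [binary_network] or igraph graph.
#' @return List with `per_node` values and their `mean`.
#' @export
clustering_coefficient <- function(net) {
  g <- .net_graph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(per_node = ci, mean = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs within the
#' largest connected component (breadth-first search per source). Computing
#' within the largest component avoids infinite distances on disconnected
#' binarized networks; the component fraction is reported alongside by
#' [small_world()] so the convention stays auditable.
#'
#' @param net A [binary_network] or igraph graph.
#' @return Mean shortest-path length `L`.
#' @export
path_length <- function(net) {
  g <- .net_graph(net)
  if (igraph::ecount(g) == 0) stop("path length undefined: network has no edges")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  igraph::mean_distance(sub, directed = FALSE, unconnected = FALSE)
}

#' Degree-preserving network randomization
#'
#' Random reference via double-edge swaps: `10 x n_edges` attempted swaps,
#' rejecting any swap that would create a self-loop or multi-edge. The degree
#' sequence is preserved exactly.
#'
#' @param net A [binary_network] or igraph graph.
#' @param seed Integer seed.
#' @return Object of the same class as the input.
#' @export
randomize_network <- function(net, seed = 1L) {
  g <- .net_graph(net)
  ne <- igraph::ecount(g)
  if (ne < 2) {
    warning("fewer than 2 edges: no degree-preserving swap possible; returning copy")
    return(net)
  }
  set.seed(seed)
  rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = 10 * ne))
  if (inherits(net, "binary_network")) {
    adj <- igraph::as_adjacency_matrix(rg, sparse = TRUE)
    binary_network(adj, origins = net$origins, threshold = net$threshold)
  } else rg
}

#' Small-world coefficient against degree-preserving random references
#'
#' Computes the clustering coefficient `C` and characteristic path length `L`
#' of the network, their means over `n_random` degree-preserving randomized
#' references, and the normalized ratios `gamma = C / C_rand`,
#' `lambda = L / L_rand`, `sigma = gamma / lambda`. Values of `sigma` above 1
#' indicate more clustered-yet-integrated structure than a random network of
#' identical degree sequence.
#'
#' @param net A [binary_network] or igraph graph.
#' @param n_random Number of randomized references (default 5).
#' @param seed Integer seed; per-reference seeds are split deterministically.
#' @return An object of class `network_metrics` with fields `n_nodes`,
#'   `n_edges`, `mean_degree`, `clustering`, `path_length`, `c_rand`,
#'   `l_rand`, `gamma`, `lambda`, `sigma`, `n_random`, `component_fraction`.
#' @export
small_world <- function(net, n_random = 5L, seed = 1L) {
  g <- .net_graph(net)
  n <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (ne == 0) stop("small-world coefficient undefined on an empty network")
  comp <- igraph::components(g)
  cf <- max(comp$csize) / n
  if (cf <= 0.5) warning("largest connected component holds <= 50% of nodes")
  C <- clustering_coefficient(g)$mean
  L <- path_length(g)
  c_r <- l_r <- rep(NA_real_, n_random)
  for (k in seq_len(n_random)) {
    rg <- randomize_network(g, seed = split_seed(seed, k))
    c_r[k] <- clustering_coefficient(rg)$mean
    l_r[k] <- tryCatch(path_length(rg), error = function(e) NA_real_)
  }
  bad <- !is.finite(l_r) | !is.finite(c_r)
  if (any(bad)) warning(sum(bad), " randomized reference(s) with undefined metrics excluded")
  if (all(bad)) stop("all randomized references undefined; cannot normalize")
  c_rand <- mean(c_r[!bad]); l_rand <- mean(l_r[!bad])
  gamma <- C / c_rand; lambda <- L / l_rand
  structure(list(n_nodes = n, n_edges = ne,
                 mean_degree = 2 * ne / n,
                 clustering = C, path_length = L,
                 c_rand = c_rand, l_rand = l_rand,
                 gamma = gamma, lambda = lambda,
                 sigma = gamma / lambda,
                 n_random = sum(!bad),
                 component_fraction = cf),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network_metrics: %d nodes, %d edges, <k> = %.2f\n",
                     "  C = %.4f  L = %.4f  gamma = %.3f  lambda = %.3f  sigma = %.3f\n",
                     "  (%d random references, %.0f%% of nodes in largest component)\n"),
              x$n_nodes, x$n_edges, x$mean_degree, x$clustering, x$path_length,
              x$gamma, x$lambda, x$sigma, x$n_random, 100 * x$component_fraction))
  invisible(x)
}
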