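#' Binary single-subject network
#'
#' An undirected, unweighted graph over included cube nodes, stored as a
#' symmetric sparse adjacency (no self-loops) with the cube origins and the
#' correlation threshold that produced it.
#'
#' @param adjacency Symmetric logical/0-1 matrix (dense or sparse), zero diagonal.
#' @param origins Integer matrix `n x 3` of 0-based cube origin voxel
#'   coordinates, one row per node (optional).
#' @param threshold Correlation threshold used for binarization (or `NA`).
#' @return An object of class `binary_network`.
#' @export
binary_network <- function(adjacency, origins = NULL, threshold = NA_real_) {
  adj <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
  adj <- Matrix::drop0(adj * 1)
  if (!Matrix::isSymmetric(adj)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(adj) != 0)) stop("adjacency must have zero diagonal")
  n <- nrow(adj)
  if (!is.null(origins)) {
    origins <- as.matrix(origins)
    dimnames(origins) <- NULL
    stopifnot(nrow(origins) == n, ncol(origins) == 3)
  }
  structure(list(adjacency = adj,
                 origins = origins,
                 threshold = threshold,
                 n_nodes = n,
                 n_edges = as.integer(Matrix::nnzero(adj) / 2)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  dens <- if (x$n_nodes > 1) x$n_edges / choose(x$n_nodes, 2) else NA_real_
  cat(sprintf("binary_network: %d nodes, %d edges (density %.4f), threshold %s\n",
              x$n_nodes, x$n_edges, dens,
              format(x$threshold, digits = 4)))
  invisible(x)
}

#' Convert a binary network to an igraph graph
#'
#' @param net A [binary_network].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Write / read a binary network as Matrix Market plus a node sidecar
#'
#' The adjacency's upper triangle is written in Matrix Market coordinate
#' format to `<prefix>.mtx`; node metadata (cube origins) and the threshold
#' go to `<prefix>_nodes.csv`. The round trip is exact.
#'
#' @param net A [binary_network].
#' @param prefix Path prefix (no extension).
#' @return `write_network` returns `prefix` invisibly; `read_network` a
#'   [binary_network].
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "binary_network"))
  ut <- Matrix::triu(net$adjacency, k = 1)
  Matrix::writeMM(ut, paste0(prefix, ".mtx"))
  ori <- net$origins
  if (is.null(ori)) ori <- matrix(NA_integer_, net$n_nodes, 3)
  nodes <- data.frame(node = seq_len(net$n_nodes),
                      ox = ori[, 1], oy = ori[, 2], oz = ori[, 3])
  con <- file(paste0(prefix, "_nodes.csv"), "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold: %.17g", net$threshold), con)
  utils::write.csv(nodes, con, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  mtx_path <- paste0(prefix, ".mtx")
  nodes_path <- paste0(prefix, "_nodes.csv")
  if (!file.exists(mtx_path)) stop("no such network file: ", mtx_path)
  ut <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  nodes <- utils::read.csv(nodes_path, comment.char = "#")
  first <- readLines(nodes_path, n = 1)
  thr <- if (grepl("^# threshold:", first)) {
    suppressWarnings(as.numeric(sub("^# threshold:\\s*", "", first)))
  } else NA_real_
  adj <- ut + Matrix::t(ut)
  ori <- as.matrix(nodes[, c("ox", "oy", "oz")])
  if (all(is.na(ori))) ori <- NULL
  binary_network(adj, origins = ori, threshold = thr)
}
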