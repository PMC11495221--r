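# Independent brute-force oracles used to validate the graph metrics and
# correlation code. Deliberately naive implementations on dense matrices.

# Watts-Strogatz local clustering by direct triangle enumeration
oracle_clustering <- function(A) {
  A <- as.matrix(A) != 0
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) next
    t <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (A[nb[a], nb[b]]) t <- t + 1
    }
    ci[i] <- 2 * t / (k * (k - 1))
  }
  ci
}

# all-pairs shortest paths by Floyd-Warshall; returns the mean distance over
# unordered pairs within the largest connected component
oracle_path_length <- function(A) {
  A <- as.matrix(A) != 0
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  # connected components from finite distances
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(D[i, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  d <- D[big, big][upper.tri(D[big, big])]
  mean(d)
}

# textbook Pearson correlation, elementwise
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Erdos-Renyi adjacency matrix
random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

adjacency_of <- function(net) as.matrix(net$adjacency)
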