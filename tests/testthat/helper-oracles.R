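# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: exhaustive enumeration for average-linkage clustering,
# and Floyd-Warshall plus a direct double-centering eigendecomposition for
# the Isomap embedding.

# Brute-force average linkage (UPGMA) on a distance matrix: at every step
# scan all cluster pairs, merge the pair with the smallest mean pairwise
# distance (ties: lexicographically lowest pair). Returns the merge
# history as member sets plus merge heights.
oracle_average_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    g <- length(clusters)
    best <- NULL
    bestd <- Inf
    for (i in seq_len(g - 1)) {
      for (j in (i + 1):g) {
        dd <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (dd < bestd) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <- sort(c(sort(clusters[[best[1]]])[1],
                                           sort(clusters[[best[2]]])[1]))
    merges[[length(merges)]] <- list(a = sort(clusters[[best[1]]]),
                                     b = sort(clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[best[2]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Decode an hclust merge table into per-step member sets.
hclust_merge_sets <- function(hc) {
  node <- vector("list", nrow(hc$merge))
  get_set <- function(k) if (k < 0) -k else node[[k]]
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    a <- sort(get_set(hc$merge[s, 1]))
    b <- sort(get_set(hc$merge[s, 2]))
    node[[s]] <- c(a, b)
    out[[s]] <- list(a = a, b = b)
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall (vectorized over k)
oracle_floyd_warshall <- function(W) {
  D <- W
  n <- nrow(D)
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# symmetric union k-NN weighted adjacency with Inf for non-edges
oracle_knn_weights <- function(D, k) {
  n <- nrow(D)
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    W[i, nb] <- D[i, nb]
    W[nb, i] <- D[nb, i]
  }
  W
}

# classical MDS by direct double centering + eigendecomposition
oracle_cmds <- function(G, d) {
  n <- nrow(G)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (G^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- seq_len(d)
  lam <- pmax(e$values[keep], 0)
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), d)
}

# full Isomap oracle: embedded inter-point distances
oracle_isomap_distances <- function(D, k, d) {
  W <- oracle_knn_weights(D, k)
  G <- oracle_floyd_warshall(W)
  stopifnot(all(is.finite(G)))
  X <- oracle_cmds(G, d)
  as.matrix(dist(X))
}

# random dissimilarity matrix from points in R^q (always metric, connected
# at any k >= 1 in the sense that geodesics stay finite for k >= 2)
random_point_dissimilarity <- function(n, q = 3) {
  X <- matrix(rnorm(n * q), n, q)
  as.matrix(dist(X))
}

# the planted axis-feature index sets of the default loading matrix
planted_feature_sets <- function() {
  W <- default_loading_matrix(3)
  lapply(1:3, function(k) which(W[k, ] != 0))
}
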