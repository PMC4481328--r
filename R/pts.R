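# Perceptual texture space: Isomap embedding of grouping dissimilarity,
# residual-variance dimensionality selection, axis-feature correlations and
# the subset robustness analysis.

#' Dissimilarity matrix from a similarity matrix
#'
#' @param S Symmetric similarity matrix with entries in \eqn{[0, 1]}.
#' @return \code{1 - S} with a zeroed diagonal.
#' @export
dissimilarity_matrix <- function(S) {
  D <- 1 - as.matrix(S)
  diag(D) <- 0
  D
}

# symmetric k-nearest-neighbor graph (union rule) as a weighted igraph
.knn_graph <- function(D, k) {
  n <- nrow(D)
  if (k < 1 || k > n - 1) stop("k_neighbors must be in [1, n-1]", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i]) # positions excluding self
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  W <- ifelse(adj, D, 0)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

# geodesic (graph shortest-path) distance matrix; errors on disconnection
.geodesic_distances <- function(D, k) {
  g <- .knn_graph(D, k)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop("neighborhood graph is disconnected (", comp$no,
         " components); increase k_neighbors", call. = FALSE)
  }
  igraph::distances(g)
}

#' Smallest connecting neighborhood size
#'
#' Returns the smallest \code{k >= k_min} whose symmetric k-nearest-neighbor
#' graph on \code{D} is connected. Co-grouping dissimilarities saturate at 1
#' for sample pairs that were never co-grouped, so an isolated perceptual
#' branch can disconnect the graph at small k; the pipeline escalates to the
#' connecting k and records it.
#'
#' @param D Hollow symmetric dissimilarity matrix.
#' @param k_min Smallest neighborhood size to try.
#' @return Integer neighborhood size.
#' @export
connecting_k <- function(D, k_min = 10L) {
  n <- nrow(D)
  k_min <- min(k_min, n - 1L)
  for (k in k_min:(n - 1)) {
    if (igraph::components(.knn_graph(D, k))$no == 1) return(k)
  }
  stop("no connected k-nearest-neighbor graph exists", call. = FALSE)
}

#' Isomap embedding of a dissimilarity matrix
#'
#' Builds the symmetric k-nearest-neighbor graph on the dissimilarities,
#' computes graph geodesics (all-pairs shortest paths), and embeds them by
#' classical (Torgerson) metric scaling. Columns are ordered by descending
#' eigenvalue; the embedding is unique only up to rigid transforms, so
#' downstream comparisons use inter-point distances or correlations.
#'
#' @param D Hollow symmetric dissimilarity matrix.
#' @param k_neighbors Neighborhood size (default 10).
#' @param d Embedding dimensionality.
#' @return \code{n x d} coordinate matrix with attributes \code{eig} (all
#'   eigenvalues) and \code{geodesic} (the geodesic distance matrix). If
#'   fewer than \code{d} positive eigenvalues exist the result is truncated
#'   with a warning.
#' @export
isomap_embed <- function(D, k_neighbors = 10L, d = 3L) {
  D <- as.matrix(D)
  if (d < 1) stop("d must be at least 1", call. = FALSE)
  geo <- .geodesic_distances(D, k_neighbors)
  n <- nrow(geo)
  mds <- stats::cmdscale(geo, k = min(d, n - 1), eig = TRUE)
  npos <- sum(mds$eig > 1e-9 * max(mds$eig))
  if (npos < d) {
    warning("only ", npos, " positive eigenvalues; truncating embedding from ",
            d, " to ", npos, " dimensions", call. = FALSE)
  }
  k <- min(d, npos)
  coords <- mds$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  attr(coords, "eig") <- mds$eig
  attr(coords, "geodesic") <- geo
  coords
}

#' Residual-variance curve over embedding dimensions
#'
#' The residual variance at dimension d is \code{1 - rho^2}, where rho is
#' the Pearson correlation between the graph geodesic distances and the
#' Euclidean distances of the d-dimensional embedding (upper triangles).
#'
#' @param D Hollow symmetric dissimilarity matrix.
#' @param k_neighbors Neighborhood size.
#' @param max_dim Highest dimension evaluated (default 10).
#' @return Numeric vector \code{RV[1..max_dim]} (shorter if fewer positive
#'   eigenvalues are available).
#' @export
residual_variance_curve <- function(D, k_neighbors = 10L, max_dim = 10L) {
  coords <- suppressWarnings(isomap_embed(D, k_neighbors, d = max_dim))
  geo <- attr(coords, "geodesic")
  ut <- upper.tri(geo)
  gvec <- geo[ut]
  vapply(seq_len(ncol(coords)), function(d) {
    e <- as.matrix(stats::dist(coords[, seq_len(d), drop = FALSE]))
    1 - stats::cor(gvec, e[ut])^2
  }, numeric(1))
}

#' Select the embedding dimensionality from a residual-variance curve
#'
#' Picks the elbow: the dimension d in \code{[2, length(curve) - 1]} (capped
#' at 9) maximizing the discrete second difference
#' \code{RV(d-1) - 2 RV(d) + RV(d+1)}; ties break toward smaller d.
#'
#' @param curve Residual variances for dimensions 1, 2, ... (length \eqn{\ge} 4).
#' @return Integer dimension.
#' @examples
#' select_dimension(c(0.60, 0.30, 0.05, 0.04, 0.03))  # 3
#' @export
select_dimension <- function(curve) {
  if (length(curve) < 4) stop("curve must cover at least 4 dimensions",
                              call. = FALSE)
  dmax <- min(9L, length(curve) - 1L)
  cand <- 2:dmax
  sd2 <- curve[cand - 1] - 2 * curve[cand] + curve[cand + 1]
  cand[which.max(sd2)]  # which.max returns the first maximum: smaller d wins
}

#' Correlate embedding axes with perceptual features
#'
#' Pearson correlation of each embedding axis with each column of the
#' sample-feature matrix. A constant feature column (or axis) yields 0 with
#' a warning.
#'
#' @param coords \code{n x d} embedding coordinates.
#' @param F_tex \code{n x 12} sample-feature matrix.
#' @return \code{d x 12} correlation matrix (rows \code{axis1..axisd}).
#' @export
axis_feature_correlations <- function(coords, F_tex) {
  coords <- as.matrix(coords)
  F_tex <- as.matrix(F_tex)
  if (nrow(coords) != nrow(F_tex)) stop("row mismatch", call. = FALSE)
  if (nrow(coords) < 3) stop("need at least 3 samples", call. = FALSE)
  out <- matrix(0, ncol(coords), ncol(F_tex),
                dimnames = list(paste0("axis", seq_len(ncol(coords))),
                                colnames(F_tex)))
  for (a in seq_len(ncol(coords))) {
    for (j in seq_len(ncol(F_tex))) {
      if (stats::sd(coords[, a]) == 0 || stats::sd(F_tex[, j]) == 0) {
        warning("constant column; correlation reported as 0", call. = FALSE)
        out[a, j] <- 0
      } else {
        out[a, j] <- stats::cor(coords[, a], F_tex[, j])
      }
    }
  }
  out
}

#' Default subset definitions for the robustness analysis
#'
#' Eight stimulus subsets: seven leave out one family of models each
#' (forest-fire automaton; the fabric-weave family; all texton models; all
#' cellular automata; the cellular model; the folding models; folding and
#' fusion models) and the eighth is the full set. Only exclusions naming
#' models present in \code{labels} apply.
#'
#' @param labels Model ids present in the dataset.
#' @return Named list of character vectors of excluded model ids.
#' @export
default_subset_definitions <- function(labels = NULL) {
  all_ids <- names(.registry$models)
  texton <- grep("^texton_", all_ids, value = TRUE)
  ca <- grep("^ca_", all_ids, value = TRUE)
  folding <- grep("^folding_", all_ids, value = TRUE)
  fusion <- grep("^fusion_", all_ids, value = TRUE)
  defs <- list(
    subset1 = "ca_forest_fire",
    subset2 = "matrix_transformation",
    subset3 = texton,
    subset4 = ca,
    subset5 = "cellular",
    subset6 = folding,
    subset7 = c(folding, fusion),
    subset8 = character(0)
  )
  if (!is.null(labels)) {
    defs <- lapply(defs, function(ex) intersect(ex, unique(labels)))
  }
  defs
}

#' Axis-feature correlations across stimulus subsets
#'
#' For each subset the rows/columns of the excluded models' samples are
#' removed from the similarity matrix, the remaining dissimilarities are
#' re-embedded at d = 3, and the axis-feature correlations recomputed.
#'
#' @param S Pooled \code{n x n} similarity matrix.
#' @param labels Model id per sample.
#' @param F_tex \code{n x 12} sample-feature matrix.
#' @param subset_definitions Named list of excluded-model-id vectors
#'   (default \code{\link{default_subset_definitions}}).
#' @param k_neighbors Isomap neighborhood size.
#' @param auto_connect Escalate each subset's neighborhood size to the
#'   smallest connecting k when the graph is disconnected at
#'   \code{k_neighbors} (default \code{TRUE}).
#' @return Named list of \code{3 x 12} correlation matrices.
#' @export
subset_analysis <- function(S, labels, F_tex,
                            subset_definitions = NULL, k_neighbors = 10L,
                            auto_connect = TRUE) {
  if (is.null(subset_definitions)) {
    subset_definitions <- default_subset_definitions(labels)
  }
  lapply(subset_definitions, function(excl) {
    keep <- !(labels %in% excl)
    if (length(unique(labels[keep])) < 3) {
      stop("subset leaves fewer than 3 models", call. = FALSE)
    }
    Dsub <- dissimilarity_matrix(S[keep, keep, drop = FALSE])
    k <- if (auto_connect) connecting_k(Dsub, k_neighbors) else k_neighbors
    coords <- isomap_embed(Dsub, k, d = 3)
    axis_feature_correlations(coords, F_tex[keep, , drop = FALSE])
  })
}
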