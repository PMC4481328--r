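# Model-level structure: average-linkage dendrogram over similarity rows,
# level cuts, and the truncated-SVD biplot of models x features.

#' Average-linkage dendrogram of procedural models
#'
#' The distance between two models is the Euclidean distance between their
#' rows of the model similarity matrix (each row is the model's similarity
#' profile against all models); agglomeration is average linkage (UPGMA).
#'
#' @param S_mod \code{m x m} model similarity matrix with model dimnames.
#' @return Object of class \code{"texspace_dendro"}: the underlying
#'   \code{\link[stats]{hclust}} tree plus leaf \code{labels}.
#' @export
hca_dendrogram <- function(S_mod) {
  S_mod <- as.matrix(S_mod)
  if (nrow(S_mod) != ncol(S_mod)) stop("S_mod must be square", call. = FALSE)
  if (max(abs(S_mod - t(S_mod))) > 1e-8) {
    stop("S_mod must be symmetric", call. = FALSE)
  }
  if (nrow(S_mod) < 2) stop("need at least 2 models", call. = FALSE)
  labs <- rownames(S_mod)
  if (is.null(labs)) labs <- paste0("model", seq_len(nrow(S_mod)))
  d <- stats::dist(S_mod)  # Euclidean distance between similarity rows
  hc <- stats::hclust(d, method = "average")
  hc$labels <- labs
  structure(list(hclust = hc, labels = labs), class = "texspace_dendro")
}

#' @export
print.texspace_dendro <- function(x, ...) {
  cat("<texspace_dendro> ", length(x$labels), " leaves, max height ",
      format(max(x$hclust$height), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.texspace_dendro <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", ...)
  invisible(x)
}

#' Cut a dendrogram at a dissimilarity level
#'
#' Clusters are the connected components formed by merges with height
#' strictly below \code{level}. The reference operating points are 7.0
#' (major clusters) and 2.5 (model merging) on the dissimilarity scale of
#' the fitted tree; see \code{\link{merge_model_classes}} for the
#' scale-relative default used by the pipeline.
#'
#' @param dendro A \code{"texspace_dendro"}.
#' @param level Dissimilarity level (\eqn{\ge} 0).
#' @return Named integer vector of cluster ids (model -> cluster), clusters
#'   numbered in order of their first leaf.
#' @export
cut_dendrogram <- function(dendro, level) {
  if (level < 0) stop("level must be non-negative", call. = FALSE)
  hc <- dendro$hclust
  m <- length(dendro$labels)
  memb <- seq_len(m)  # union-find by relabel (m is small)
  node <- vector("list", nrow(hc$merge))
  leaf <- function(k) if (k < 0) -k else node[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    a <- leaf(hc$merge[s, 1])
    b <- leaf(hc$merge[s, 2])
    node[[s]] <- c(a, b)
    if (hc$height[s] < level) {
      memb[memb %in% memb[b]] <- memb[a[1]]
    }
  }
  ids <- match(memb, unique(memb))
  names(ids) <- dendro$labels
  ids
}

#' Rank-3 singular value decomposition of the model-feature matrix
#'
#' Decomposes the model-feature matrix and keeps the three leading singular
#' triplets: \code{U3} (m x 3) spans the model side, \code{V3} (12 x 3) the
#' feature side, and \code{U3 diag(Sigma3) V3'} is the best rank-3
#' approximation of the matrix in Frobenius norm (equivalently, its
#' transpose approximates the feature-by-model matrix).
#'
#' @param F_mod \code{m x 12} model-feature matrix.
#' @return Object of class \code{"texspace_svd"}: \code{U3}, \code{Sigma3}
#'   (descending, length 3), \code{V3}, plus the full singular values
#'   \code{sigma_all}.
#' @export
svd_embed <- function(F_mod) {
  F_mod <- as.matrix(F_mod)
  if (!all(is.finite(F_mod))) stop("F_mod must be finite", call. = FALSE)
  if (all(F_mod == 0)) stop("F_mod has rank 0", call. = FALSE)
  sv <- svd(F_mod)
  k <- min(3L, length(sv$d))
  U3 <- sv$u[, seq_len(k), drop = FALSE]
  V3 <- sv$v[, seq_len(k), drop = FALSE]
  rownames(U3) <- rownames(F_mod)
  rownames(V3) <- colnames(F_mod)
  structure(list(U3 = U3, Sigma3 = sv$d[seq_len(k)], V3 = V3,
                 sigma_all = sv$d),
            class = "texspace_svd")
}

#' Joint biplot coordinates of models and features
#'
#' Takes columns 2 and 3 of the model-side and feature-side singular
#' vectors verbatim (the first column reflects overall rating magnitude and
#' carries no contrast between models or features, so it is dropped).
#'
#' @param svd A \code{"texspace_svd"}.
#' @return List with \code{models} (m x 2) and \code{features} (12 x 2)
#'   coordinate matrices, rows named.
#' @export
biplot_coordinates <- function(svd) {
  if (ncol(svd$U3) < 3) {
    stop("need three retained singular vectors for the biplot", call. = FALSE)
  }
  list(models = svd$U3[, 2:3, drop = FALSE],
       features = svd$V3[, 2:3, drop = FALSE])
}
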