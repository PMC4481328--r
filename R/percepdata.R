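# Construction of the four core matrices from experimental records:
# pooled sample similarity S, model-level similarity S_mod, sample-feature
# matrix F_tex and model-feature matrix F_mod.

# partition (list of index vectors) -> n x n co-membership indicator
.comembership <- function(groups, n) {
  memb <- integer(n)
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  outer(memb, memb, "==") * 1
}

#' Pooled co-grouping similarity matrix
#'
#' For each subject the stage partitions are the initial partition plus the
#' partition after each recorded merge, excluding the final all-in-one
#' stage. The subject's similarity between samples i and j is the fraction
#' of those stages in which i and j share a group; pooling averages over
#' subjects. The diagonal is fixed at 1. Counting per subject and excluding
#' the terminal single cluster keeps entries in \eqn{[0, 1]} with 0 reachable
#' (a pair never co-grouped before the final stage).
#'
#' @param records List of grouping records (see
#'   \code{\link{simulate_grouping}}).
#' @param n Number of samples; every record must cover samples 1..n exactly.
#' @return \code{n x n} symmetric similarity matrix with unit diagonal.
#' @export
pooled_similarity <- function(records, n) {
  if (length(records) == 0) stop("no grouping records", call. = FALSE)
  acc <- matrix(0, n, n)
  for (rec in records) {
    covered <- sort(as.integer(unlist(rec$groups)))
    if (!identical(covered, seq_len(n))) {
      stop("record for subject ", rec$subject,
           " does not cover samples 1..n exactly once", call. = FALSE)
    }
    groups <- rec$groups
    n_stages <- 1L + length(rec$merges) - 1L  # initial + merges, minus final
    if (n_stages < 1L) stop("zero countable stages (single initial group)",
                            call. = FALSE)
    cm <- .comembership(groups, n)
    for (m in rec$merges) {
      if (length(groups) == 2L) break  # next merge is the excluded final stage
      a <- m[1]
      b <- m[2]
      groups[[a]] <- c(groups[[a]], groups[[b]])
      groups[b] <- NULL
      cm <- cm + .comembership(groups, n)
    }
    acc <- acc + cm / n_stages
  }
  s <- acc / length(records)
  diag(s) <- 1
  s
}

#' Model-level similarity matrix
#'
#' Entry (u, v) is the mean of the sample similarity over pairs with one
#' sample from model u and one from model v; within-model blocks exclude the
#' diagonal (self-pairs).
#'
#' @param S \code{n x n} pooled similarity matrix.
#' @param labels Model id per sample (length n).
#' @return \code{m x m} symmetric matrix with model ids as dimnames.
#' @export
model_similarity <- function(S, labels) {
  n <- nrow(S)
  if (length(labels) != n) stop("labels length must match S", call. = FALSE)
  mods <- unique(labels)
  m <- length(mods)
  out <- matrix(0, m, m, dimnames = list(mods, mods))
  idx <- split(seq_len(n), factor(labels, levels = mods))
  for (u in seq_len(m)) {
    for (v in u:m) {
      block <- S[idx[[u]], idx[[v]], drop = FALSE]
      if (u == v) {
        k <- length(idx[[u]])
        if (k < 2) {
          stop("model '", mods[u],
               "' has fewer than 2 samples; within-model mean undefined",
               call. = FALSE)
        }
        val <- (sum(block) - sum(diag(block))) / (k * (k - 1))
      } else {
        val <- mean(block)
      }
      out[u, v] <- val
      out[v, u] <- val
    }
  }
  out
}

#' Sample-feature matrix from a rating tensor
#'
#' Averages each sample's feature ratings over the subjects who rated it
#' (entries may be \code{NA} for subjects who did not rate a sample, e.g.
#' when raters are assigned subsets of the stimuli).
#'
#' @param ratings Array \code{subjects x samples x 12} (integers 1..9 or
#'   \code{NA}).
#' @return \code{n x 12} matrix of mean scales in \eqn{[1, 9]}, columns in
#'   schema order.
#' @export
sample_feature_matrix <- function(ratings) {
  if (length(dim(ratings)) != 3 || dim(ratings)[3] != 12) {
    stop("ratings must be a subjects x samples x 12 array", call. = FALSE)
  }
  out <- apply(ratings, c(2, 3), mean, na.rm = TRUE)
  if (any(!is.finite(out))) {
    stop("some sample/feature cells were rated by nobody", call. = FALSE)
  }
  colnames(out) <- dimnames(ratings)[[3]]
  if (is.null(colnames(out))) colnames(out) <- feature_schema()$feature
  out
}

#' Model-feature matrix
#'
#' Row per model: mean of its samples' rows of the sample-feature matrix.
#'
#' @param F_tex \code{n x 12} sample-feature matrix.
#' @param labels Model id per sample.
#' @return \code{m x 12} matrix with model ids as rownames.
#' @export
model_feature_matrix <- function(F_tex, labels) {
  if (length(labels) != nrow(F_tex)) {
    stop("labels length must match F_tex rows", call. = FALSE)
  }
  mods <- unique(labels)
  out <- t(vapply(mods, function(mod) {
    colMeans(F_tex[labels == mod, , drop = FALSE])
  }, numeric(ncol(F_tex))))
  rownames(out) <- mods
  colnames(out) <- colnames(F_tex)
  out
}
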