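# Mapping between perceptual scales and the perceptual texture space:
# per-axis feature selection, kernel regression onto the space, model-class
# merging, leave-one-out classification, similarity-consistency correlation
# and the model-recommendation endpoint.

#' Select per-axis feature subsets from a correlation table
#'
#' Each axis keeps the features whose absolute correlation with it reaches
#' \code{threshold}; if none qualify the two largest-|r| features are kept
#' with a warning.
#'
#' @param corr \code{3 x 12} axis-feature correlation matrix.
#' @param threshold Absolute-correlation threshold in \eqn{[0, 1)};
#'   default 0.40.
#' @return List of three integer vectors of feature column indices.
#' @export
select_axis_features <- function(corr, threshold = 0.40) {
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  lapply(seq_len(nrow(corr)), function(a) {
    r <- abs(corr[a, ])
    sel <- which(r >= threshold)
    if (length(sel) == 0) {
      warning("axis ", a, ": no feature reaches |r| >= ", threshold,
              "; falling back to the top 2", call. = FALSE)
      sel <- order(r, decreasing = TRUE)[1:2]
    }
    sort(unname(sel))
  })
}

# k-fold assignment, seeded and balanced
.cv_folds <- function(n, k, seed) {
  .with_seed(.hash_seed(seed, "folds", n, k), {
    sample(rep_len(seq_len(k), n))
  })
}

# radial-kernel SVR with a small inner grid search over (cost, gamma);
# returns the refitted model and pooled held-out predictions
.svr_grid <- function(x, y, folds, seed) {
  p <- ncol(x)
  if (stats::sd(y) == 0) {
    # degenerate constant target: predict the constant
    return(list(model = structure(list(value = y[1]), class = "ts_constfit"),
                cost = NA_real_, gamma = NA_real_,
                cv_pred = rep(y[1], length(y)), cv_mse = 0))
  }
  grid <- expand.grid(cost = c(1, 10, 100), gamma = c(0.5, 1, 2) / p)
  fold_id <- .cv_folds(length(y), folds, seed)
  best <- NULL
  best_mse <- Inf
  best_pred <- NULL
  for (g in seq_len(nrow(grid))) {
    pred <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "eps-regression",
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], epsilon = 0.01)
      pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
    }
    mse <- mean((pred - y)^2)
    if (mse < best_mse) {
      best_mse <- mse
      best <- grid[g, ]
      best_pred <- pred
    }
  }
  final <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                      cost = best$cost, gamma = best$gamma, epsilon = 0.01)
  list(model = final, cost = best$cost, gamma = best$gamma,
       cv_pred = best_pred, cv_mse = best_mse)
}

#' Fit per-axis kernel regressions from perceptual scales to the space
#'
#' One radial-kernel support vector regression per embedding axis, trained
#' on that axis's selected feature subset. Coordinates are standardized to
#' zero mean and unit variance before fitting so that reported mean squared
#' errors are scale-comparable across axes; held-out performance (pooled
#' over cross-validation folds at the selected hyperparameters) is reported
#' as MSE and squared correlation.
#'
#' @param F_tex \code{n x 12} sample-feature matrix.
#' @param coords \code{n x d} embedding coordinates.
#' @param subsets List of per-axis feature index vectors
#'   (\code{\link{select_axis_features}}).
#' @param cv_folds Number of folds for the inner grid search (default 5).
#' @param seed RNG seed for fold assignment.
#' @return Object of class \code{"texspace_regressors"}: fitted models,
#'   subsets, standardization parameters, and a \code{report} data frame
#'   with per-axis held-out \code{mse} and \code{r_squared}.
#' @export
fit_axis_regressors <- function(F_tex, coords, subsets, cv_folds = 5L,
                                seed = 1L) {
  F_tex <- as.matrix(F_tex)
  coords <- as.matrix(coords)
  n <- nrow(F_tex)
  if (n != nrow(coords)) stop("row mismatch", call. = FALSE)
  if (n < 2 * cv_folds) stop("need n >= 2 * cv_folds", call. = FALSE)
  d <- ncol(coords)
  if (length(subsets) != d) stop("one feature subset per axis", call. = FALSE)
  ctr <- colMeans(coords)
  scl <- apply(coords, 2, stats::sd)
  scl[scl == 0] <- 1
  models <- vector("list", d)
  report <- data.frame(axis = paste0("axis", seq_len(d)), mse = NA_real_,
                       r_squared = NA_real_, cost = NA_real_, gamma = NA_real_)
  for (a in seq_len(d)) {
    y <- (coords[, a] - ctr[a]) / scl[a]
    x <- F_tex[, subsets[[a]], drop = FALSE]
    fit <- .svr_grid(x, y, cv_folds, .hash_seed(seed, "axis", a))
    models[[a]] <- fit
    report$mse[a] <- fit$cv_mse
    if (stats::sd(y) == 0 || stats::sd(fit$cv_pred) == 0) {
      warning("axis ", a, ": degenerate target or prediction; ",
              "squared correlation reported as 0", call. = FALSE)
      report$r_squared[a] <- 0
    } else {
      report$r_squared[a] <- stats::cor(fit$cv_pred, y)^2
    }
    report$cost[a] <- fit$cost
    report$gamma[a] <- fit$gamma
  }
  structure(list(models = models, subsets = subsets, center = ctr,
                 scale = scl, report = report, n_features = ncol(F_tex)),
            class = "texspace_regressors")
}

#' @export
print.texspace_regressors <- function(x, ...) {
  cat("<texspace_regressors> ", length(x$models), " axes\n", sep = "")
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict perceptual-space coordinates from perceptual scales
#'
#' @param regressors A fitted \code{"texspace_regressors"}.
#' @param scales Numeric vector of 12 perceptual scales in \eqn{[1, 9]}, or
#'   a matrix with 12 columns for batch prediction.
#' @return Matrix of predicted coordinates (rows = inputs, columns = axes),
#'   in the standardized units of the fitted space.
#' @export
predict_pts <- function(regressors, scales) {
  if (!inherits(regressors, "texspace_regressors")) {
    stop("regressors must come from fit_axis_regressors()", call. = FALSE)
  }
  if (is.null(dim(scales))) scales <- matrix(scales, nrow = 1)
  scales <- as.matrix(scales)
  if (ncol(scales) != regressors$n_features) {
    stop("scales must have ", regressors$n_features, " columns", call. = FALSE)
  }
  if (any(!is.finite(scales)) || any(scales < 1 | scales > 9)) {
    stop("scales must lie within [1, 9]", call. = FALSE)
  }
  out <- vapply(seq_along(regressors$models), function(a) {
    x <- scales[, regressors$subsets[[a]], drop = FALSE]
    m <- regressors$models[[a]]$model
    if (inherits(m, "ts_constfit")) return(rep(m$value, nrow(x)))
    as.numeric(stats::predict(m, x))
  }, numeric(nrow(scales)))
  out <- matrix(out, nrow = nrow(scales))
  colnames(out) <- paste0("axis", seq_along(regressors$models))
  out
}

#' Merge procedural models into classes at a dendrogram level
#'
#' Models joined below the given dissimilarity level form one class; the
#' conventional operating point from the reference study design is 2.5. When
#' \code{relative = TRUE} the level is interpreted as a fraction of the
#' maximum merge height, which keeps the cut meaningful across similarity
#' scales.
#'
#' @param dendro A \code{"texspace_dendro"}.
#' @param level Cut level (absolute, or fraction of max height).
#' @param relative Interpret \code{level} as a fraction of the maximum
#'   merge height (default \code{FALSE}).
#' @return Named integer vector: model id -> class label (stable ordering).
#' @export
merge_model_classes <- function(dendro, level = 2.5, relative = FALSE) {
  if (relative) level <- level * max(dendro$hclust$height)
  cut_dendrogram(dendro, level)
}

#' Leave-one-out classification of samples into model classes
#'
#' Radial-kernel multiclass support vector classification; each sample is
#' predicted by a classifier trained on all others. Single-member classes
#' are kept but flagged (they cannot be predicted correctly by
#' construction).
#'
#' @param features \code{n x p} feature matrix (raw perceptual scales or
#'   embedding coordinates).
#' @param classes Class label per sample.
#' @param seed RNG seed (e1071 uses randomness internally).
#' @return List with \code{accuracy}, \code{confusion} (true x predicted),
#'   \code{predicted}, and \code{singleton_classes}.
#' @export
loo_classify <- function(features, classes, seed = 1L) {
  x <- as.matrix(features)
  y <- factor(classes)
  n <- nrow(x)
  if (length(y) != n) stop("classes length must match features", call. = FALSE)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  singletons <- names(which(table(y) == 1))
  if (length(singletons)) {
    warning("singleton class(es) present: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- .with_seed(.hash_seed(seed, "loo", i), {
      e1071::svm(x[-i, , drop = FALSE], droplevels(y[-i]),
                 type = "C-classification", kernel = "radial",
                 cost = 10, gamma = 1 / ncol(x))
    })
    pred[i] <- as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }
  list(accuracy = mean(pred == y),
       confusion = table(true = y, predicted = pred),
       predicted = pred,
       singleton_classes = singletons)
}

#' Consistency correlation between similarity and a representation
#'
#' Absolute Pearson correlation between the strict upper triangle of the
#' similarity matrix and the corresponding pairwise Euclidean distances of
#' the representation. Similarity and distance are oppositely signed by
#' construction, so the magnitude is reported.
#'
#' @param S \code{n x n} similarity matrix.
#' @param representation \code{n x p} matrix (feature scales or embedding
#'   coordinates).
#' @return Absolute correlation coefficient.
#' @export
consistency_correlation <- function(S, representation) {
  S <- as.matrix(S)
  rep_m <- as.matrix(representation)
  if (nrow(S) != nrow(rep_m)) stop("row mismatch", call. = FALSE)
  dm <- as.matrix(stats::dist(rep_m))
  ut <- upper.tri(S)
  if (stats::sd(dm[ut]) == 0) {
    stop("representation is constant; correlation undefined", call. = FALSE)
  }
  abs(stats::cor(S[ut], dm[ut]))
}

# Match recovered axes to reference axes (e.g. the planted loading pattern)
# by maximal mean |r| over each reference axis's feature set; returns the
# permutation perm with perm[k] = recovered axis assigned to reference k.
.match_axes <- function(corr, ref_sets) {
  k <- length(ref_sets)
  perms <- .permutations(k)
  best <- perms[[1]]
  best_score <- -Inf
  for (p in perms) {
    sc <- sum(vapply(seq_len(k), function(i) {
      mean(abs(corr[p[i], ref_sets[[i]]]))
    }, numeric(1)))
    if (sc > best_score) {
      best_score <- sc
      best <- p
    }
  }
  best
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in .permutations(k - 1L)) {
      tail <- seq_len(k)[-i][rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}
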