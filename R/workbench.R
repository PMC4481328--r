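# Pipeline orchestration. texspace_fit() is the package's central fitting
# function: it runs dataset assembly, the synthetic observer, matrix
# construction, HCA/SVD, the Isomap space, the regression/classification
# layer, and returns a classed object with the usual modelling methods.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end study. Defaults mirror the
#' reference study design: 512-px height maps, slant 45 / tilt 135
#' illumination, 20 grouping subjects, 58 rating subjects, 9-point Likert
#' ratings on 12 features, Isomap residual variance over dimensions 1-10,
#' and dendrogram cuts at 0.70 and 0.25 of the maximum merge height (the
#' reference operating points 7 and 2.5 expressed scale-relatively).
#'
#' @param counts Named vector of per-model sample counts (default
#'   \code{\link{default_model_counts}}, 450 samples over 23 models).
#' @param size Height-map pixels per side.
#' @param images Materialize height maps and renders (\code{FALSE} runs the
#'   perceptual analysis from the design manifest alone).
#' @param light A \code{\link{light_config}}.
#' @param D Planted latent dimensionality.
#' @param center_scale Per-axis sd of model centers (graded salience).
#' @param spread Within-model latent scatter sd.
#' @param sweep_amp Axis-1 sweep offset amplitude.
#' @param loadings \code{D x 12} loading matrix (default
#'   \code{\link{default_loading_matrix}}).
#' @param n_grouping_subjects,n_rating_subjects Simulated subject counts.
#' @param perceptual_noise Grouping coordinate noise sd.
#' @param k_init Initial group count for the grouping simulation.
#' @param rating_noise_sd Likert rating noise sd.
#' @param k_neighbors Isomap neighborhood size.
#' @param max_dims Highest dimension of the residual-variance curve.
#' @param corr_threshold |r| threshold for per-axis feature selection.
#' @param cut_major,cut_merge Dendrogram cut levels as fractions of the
#'   maximum merge height.
#' @param cv_folds Folds for the regression grid search.
#' @param master_seed Master seed fanned out to every stage.
#' @return Object of class \code{"texspace_config"}.
#' @export
texspace_config <- function(counts = default_model_counts(),
                            size = 512L,
                            images = FALSE,
                            light = light_config(),
                            D = 3L,
                            center_scale = c(2.7, 2.0, 1.7),
                            spread = 1.1,
                            sweep_amp = 1,
                            loadings = NULL,
                            n_grouping_subjects = 20L,
                            n_rating_subjects = 58L,
                            perceptual_noise = 0.8,
                            k_init = 100L,
                            rating_noise_sd = 1,
                            k_neighbors = 20L,
                            max_dims = 10L,
                            corr_threshold = 0.40,
                            cut_major = 0.70,
                            cut_merge = 0.25,
                            cv_folds = 5L,
                            master_seed = 1L) {
  ids <- names(counts)
  if (is.null(ids)) stop("counts must be named by model id", call. = FALSE)
  for (id in ids) .get_model(id)
  if (master_seed < 0) stop("master_seed must be non-negative", call. = FALSE)
  if (cut_major < 0 || cut_merge < 0) stop("cut levels must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "texspace_config")
}

#' Default reduced study configuration
#'
#' The package's standard synthetic study: the first 20 registry models with
#' 10 samples each (200 textures) at 64 px, all observer and analysis
#' parameters at their defaults. This is the configuration the package's
#' simulation-based validation runs at.
#'
#' @param master_seed Master seed.
#' @param ... Overrides passed on to \code{\link{texspace_config}}.
#' @return A \code{"texspace_config"}.
#' @export
default_synthetic_config <- function(master_seed = 1L, ...) {
  ids <- names(.registry$models)[1:20]
  counts <- stats::setNames(rep(10L, 20), ids)
  texspace_config(counts = counts, size = 64L, master_seed = master_seed, ...)
}

#' Fit the perceptual texture space pipeline
#'
#' Runs the full analysis in order: dataset assembly (and optionally height
#' map generation and Lambertian rendering), the synthetic grouping and
#' rating experiments, construction of the pooled similarity and feature
#' matrices, the average-linkage dendrogram with level cuts, the truncated
#' SVD biplot, the Isomap perceptual texture space with residual-variance
#' dimension selection, axis-feature correlations with per-axis feature
#' selection, per-axis kernel regressions, leave-one-out classification
#' with raw scales and with space coordinates, the similarity-consistency
#' correlations, and the final recommendation classifier. Deterministic
#' given the configuration's master seed.
#'
#' @param config A \code{\link{texspace_config}}.
#' @return Object of class \code{"texspace"}; see the package vignette for
#'   the component list. Use \code{print}, \code{summary}, \code{plot},
#'   \code{predict} and \code{\link{recommend_model}} on it.
#' @export
texspace_fit <- function(config = default_synthetic_config()) {
  if (!inherits(config, "texspace_config")) {
    stop("config must be a texspace_config()", call. = FALSE)
  }
  seed <- config$master_seed

  dataset <- build_dataset(config$counts, size = config$size,
                           master_seed = seed,
                           materialize = config$images)
  renders <- NULL
  if (config$images) {
    renders <- lapply(dataset$samples, render_lambertian, light = config$light)
  }
  n <- length(dataset$labels)

  latent <- plant_latent_space(dataset, D = config$D,
                               center_scale = config$center_scale,
                               spread = config$spread,
                               sweep_amp = config$sweep_amp,
                               seed = seed)
  loadings <- config$loadings
  if (is.null(loadings)) loadings <- default_loading_matrix(config$D)

  records <- simulate_grouping(latent,
                               n_subjects = config$n_grouping_subjects,
                               perceptual_noise = config$perceptual_noise,
                               k_init = config$k_init, seed = seed)
  ratings <- simulate_ratings(latent, loadings,
                              noise_sd = config$rating_noise_sd,
                              n_subjects = config$n_rating_subjects,
                              seed = seed)

  S <- pooled_similarity(records, n)
  S_mod <- model_similarity(S, dataset$labels)
  F_tex <- sample_feature_matrix(ratings)
  F_mod <- model_feature_matrix(F_tex, dataset$labels)

  dendro <- hca_dendrogram(S_mod)
  major_clusters <- merge_model_classes(dendro, config$cut_major, relative = TRUE)
  class_map <- merge_model_classes(dendro, config$cut_merge, relative = TRUE)

  svd3 <- svd_embed(F_mod)
  biplot <- biplot_coordinates(svd3)

  Dmat <- dissimilarity_matrix(S)
  k_eff <- connecting_k(Dmat, config$k_neighbors)
  rv <- residual_variance_curve(Dmat, k_eff, config$max_dims)
  dim_selected <- select_dimension(rv)
  coords <- isomap_embed(Dmat, k_eff, d = 3)

  corr <- axis_feature_correlations(coords, F_tex)
  subsets <- select_axis_features(corr, config$corr_threshold)
  regressors <- fit_axis_regressors(F_tex, coords, subsets,
                                    cv_folds = config$cv_folds, seed = seed)

  coords_std <- sweep(sweep(coords, 2, regressors$center), 2,
                      regressors$scale, "/")
  sample_classes <- factor(class_map[dataset$labels])
  loo_space <- loo_classify(coords_std, sample_classes, seed = seed)
  loo_scales <- loo_classify(F_tex, sample_classes, seed = seed)

  consistency <- c(space = consistency_correlation(S, coords),
                   scales = consistency_correlation(S, F_tex))

  class_svm <- .with_seed(.hash_seed(seed, "classmap-svm"), {
    e1071::svm(coords_std, sample_classes, type = "C-classification",
               kernel = "radial", cost = 10, gamma = 1 / ncol(coords_std),
               probability = TRUE)
  })

  # per-model swept parameter ranges for recommendation reports
  param_ranges <- lapply(split(dataset$manifest, dataset$labels), function(ps) {
    vals <- do.call(rbind, lapply(ps, `[[`, "values"))
    apply(vals, 2, range)
  })

  structure(list(
    config = config,
    dataset = dataset,
    renders = renders,
    latent = latent,
    loadings = loadings,
    records = records,
    ratings = ratings,
    S = S, S_mod = S_mod, F_tex = F_tex, F_mod = F_mod,
    dendrogram = dendro,
    major_clusters = major_clusters,
    class_map = class_map,
    svd = svd3,
    biplot = biplot,
    rv_curve = rv,
    k_neighbors_used = k_eff,
    dim_selected = dim_selected,
    coords = coords,
    coords_std = coords_std,
    correlations = corr,
    feature_subsets = subsets,
    regressors = regressors,
    loo = list(space = loo_space, scales = loo_scales),
    consistency = consistency,
    class_svm = class_svm,
    param_ranges = param_ranges
  ), class = "texspace")
}

#' @export
print.texspace <- function(x, ...) {
  n <- length(x$dataset$labels)
  m <- length(unique(x$dataset$labels))
  cat("Perceptual texture space fit\n")
  cat(sprintf("  %d samples from %d procedural models (seed %d)\n",
              n, m, x$config$master_seed))
  cat(sprintf("  selected dimensionality: %d (residual variance at 3: %.4f)\n",
              x$dim_selected, x$rv_curve[3]))
  cat(sprintf("  merged model classes at %.2f of max height: %d\n",
              x$config$cut_merge, length(unique(x$class_map))))
  cat(sprintf("  LOO accuracy: %.1f%% (space), %.1f%% (raw scales)\n",
              100 * x$loo$space$accuracy, 100 * x$loo$scales$accuracy))
  cat(sprintf("  consistency |r|: %.4f (space), %.4f (raw scales)\n",
              x$consistency["space"], x$consistency["scales"]))
  invisible(x)
}

#' @export
summary.texspace <- function(object, ...) {
  print(object)
  cat("\nResidual variance by dimension:\n")
  print(round(object$rv_curve, 4))
  cat("\nPer-axis selected features (|r| >=",
      object$config$corr_threshold, "):\n")
  feats <- colnames(object$correlations)
  for (a in seq_along(object$feature_subsets)) {
    cat(sprintf("  axis %d: %s\n", a,
                paste(feats[object$feature_subsets[[a]]], collapse = ", ")))
  }
  cat("\nRegression report (standardized coordinates):\n")
  print(object$regressors$report, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Predict space coordinates for new perceptual scale vectors
#'
#' @param object A fitted \code{"texspace"}.
#' @param newdata 12-vector or matrix with 12 columns of Likert scales in
#'   \eqn{[1, 9]}.
#' @param ... Unused.
#' @return Matrix of predicted coordinates.
#' @export
predict.texspace <- function(object, newdata, ...) {
  predict_pts(object$regressors, newdata)
}

#' @export
plot.texspace <- function(x, which = c("rv", "biplot", "dendrogram", "space"),
                          ...) {
  which <- match.arg(which)
  if (which == "rv") {
    plot(seq_along(x$rv_curve), x$rv_curve, type = "b", pch = 19,
         xlab = "Isomap dimensionality", ylab = "residual variance", ...)
    graphics::abline(v = x$dim_selected, lty = 2)
  } else if (which == "biplot") {
    b <- x$biplot
    lim <- range(c(b$models, b$features))
    plot(b$models, pch = 8, col = "blue", xlim = lim, ylim = lim,
         xlab = "component 2", ylab = "component 3", ...)
    graphics::points(b$features, pch = 1, col = "red")
    graphics::text(b$features, labels = rownames(b$features), pos = 3,
                   cex = 0.7, col = "red")
    graphics::text(b$models, labels = rownames(b$models), pos = 1, cex = 0.6)
  } else if (which == "dendrogram") {
    plot(x$dendrogram, ...)
  } else {
    cls <- factor(x$major_clusters[x$dataset$labels])
    plot(x$coords[, 1], x$coords[, 2], col = as.integer(cls), pch = 19,
         xlab = "axis 1", ylab = "axis 2", ...)
  }
  invisible(x)
}

#' Recommend procedural models for target perceptual scales
#'
#' Maps the user's 12 perceptual scales into the fitted space with the
#' per-axis regressors, scores every merged model class with the space
#' classifier, and returns the classes ranked by score (ties broken by
#' class size, then class id), each with its member models and their swept
#' parameter ranges.
#'
#' @param fit A fitted \code{"texspace"}.
#' @param user_scales Numeric 12-vector of Likert scales in \eqn{[1, 9]}.
#' @return Data frame ranked by score with columns \code{class},
#'   \code{score}, \code{members}; the full per-class detail (member models
#'   and parameter ranges) is attached as attribute \code{"detail"}, and the
#'   predicted coordinates as \code{"coords"}.
#' @export
recommend_model <- function(fit, user_scales) {
  if (!inherits(fit, "texspace")) stop("fit must be a texspace object",
                                       call. = FALSE)
  coords <- predict_pts(fit$regressors, user_scales)
  pr <- stats::predict(fit$class_svm, coords, probability = TRUE)
  prob <- attr(pr, "probabilities")[1, ]
  classes <- names(prob)
  sizes <- table(factor(fit$class_map, levels = classes))[classes]
  ord <- order(-prob, -as.integer(sizes), classes)
  members <- split(names(fit$class_map), fit$class_map)
  out <- data.frame(
    class = classes[ord],
    score = as.numeric(prob[ord]),
    members = vapply(classes[ord], function(cl) {
      paste(members[[cl]], collapse = ", ")
    }, ""),
    row.names = NULL
  )
  detail <- lapply(classes[ord], function(cl) {
    mods <- members[[cl]]
    list(models = mods, param_ranges = fit$param_ranges[mods])
  })
  names(detail) <- classes[ord]
  attr(out, "detail") <- detail
  attr(out, "coords") <- coords
  out
}
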