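# Synthetic observer: stand-in for the (undeposited) human grouping and
# rating data. Subjects are simulated from a planted low-dimensional latent
# space; the downstream analysis must be able to recover the planted
# dimensionality and axis-feature loading pattern.

#' The 12-feature perceptual rating schema
#'
#' Twelve bipolar perceptual features rated on 9-point Likert scales, in
#' fixed order, each with low (scale 1) and high (scale 9) anchor adjectives.
#'
#' @return Data frame with columns \code{feature}, \code{low}, \code{high}.
#' @export
feature_schema <- function() {
  data.frame(
    feature = c("contrast", "repetition", "granularity", "randomness",
                "roughness", "feature_density", "directionality",
                "structural_complexity", "coarseness", "regularity",
                "local_orientation", "uniformity"),
    low = c("low contrast", "non-repetitive", "non-granular", "non-random",
            "rough", "low feature density", "non-directional",
            "low structural complexity", "coarse", "irregular",
            "non-oriented", "non-uniform"),
    high = c("high contrast", "repetitive", "granular", "random", "smooth",
             "high feature density", "directional",
             "high structural complexity", "fine", "regular",
             "locally oriented", "uniform"),
    stringsAsFactors = FALSE
  )
}

#' Default latent-axis to feature loading matrix
#'
#' Encodes the three-axis association pattern the analysis is expected to
#' recover: axis 1 loads on feature density and coarseness; axis 2 loads
#' positively on repetition, directionality, regularity, local orientation
#' and uniformity and negatively on randomness; axis 3 loads on contrast,
#' granularity and structural complexity.
#'
#' @param D Number of latent axes (extra axes beyond 3 get zero loadings).
#' @return \code{D x 12} numeric matrix with feature-named columns.
#' @export
default_loading_matrix <- function(D = 3) {
  feats <- feature_schema()$feature
  W <- matrix(0, max(D, 3), 12, dimnames = list(NULL, feats))
  W[1, c("feature_density", "coarseness")] <- 1
  W[2, c("repetition", "directionality", "regularity",
         "local_orientation", "uniformity")] <- 1
  W[2, "randomness"] <- -1
  W[3, c("contrast", "granularity", "structural_complexity")] <- 1
  W[seq_len(D), , drop = FALSE]
}

#' Plant a latent perceptual space over a texture dataset
#'
#' Each model gets an isotropic Gaussian center (axis k has sd
#' \code{center_scale[k]}); each sample sits at its model center plus
#' within-model Gaussian scatter (sd \code{spread}) plus a deterministic
#' offset along axis 1 proportional to its centered normalized sweep
#' position (amplitude \code{sweep_amp}), emulating the perceptual drift of
#' a linear parameter sweep.
#'
#' @param dataset A \code{"texspace_dataset"} (manifest is sufficient).
#' @param D Latent dimensionality (default 3).
#' @param center_scale Per-axis sd of model centers; recycled to length
#'   \code{D}. The default grades axis salience downward.
#' @param spread Within-model scatter sd.
#' @param sweep_amp Amplitude of the axis-1 sweep offset.
#' @param seed RNG seed.
#' @return \code{n x D} matrix of latent coordinates with attributes
#'   \code{labels} and \code{seed}.
#' @export
plant_latent_space <- function(dataset, D = 3,
                               center_scale = c(2.7, 2.0, 1.7),
                               spread = 1.1, sweep_amp = 1, seed = 1L) {
  n <- length(dataset$labels)
  if (n == 0) stop("empty dataset", call. = FALSE)
  if (D < 1) stop("D must be at least 1", call. = FALSE)
  if (any(center_scale <= 0) || spread <= 0) {
    stop("center_scale and spread must be positive", call. = FALSE)
  }
  cs <- rep_len(center_scale, D)
  labs <- dataset$labels
  mods <- unique(labs)
  z <- .with_seed(.hash_seed(seed, "latent"), {
    m <- length(mods)
    centers <- sweep(matrix(stats::rnorm(m * D), m, D), 2, cs, "*")
    rownames(centers) <- mods
    zz <- centers[labs, , drop = FALSE] +
      matrix(stats::rnorm(n * D, 0, spread), n, D)
    if (m >= 3 * D) {
      # Whiten the realized cloud: rotate to its principal axes and rescale
      # so the sample covariance is exactly diag(cs^2 + spread^2). The
      # planted axes are then identifiable by construction (recoverable by
      # an embedding up to sign/order), which a merely in-expectation
      # anisotropic plant cannot guarantee at realistic model counts.
      # Skipped when there are too few model centers to span the axes
      # non-degenerately (small designs keep the raw Gaussian draw).
      zz <- scale(zz, center = TRUE, scale = FALSE)
      sv <- svd(zz)
      zz <- sqrt(n - 1) * sweep(sv$u[, seq_len(D), drop = FALSE], 2,
                                sqrt(cs^2 + spread^2), "*")
    }
    zz
  })
  pos <- dataset$sweep_position
  if (!is.null(pos)) z[, 1] <- z[, 1] + sweep_amp * (pos - 0.5)
  dimnames(z) <- list(NULL, paste0("axis", seq_len(D)))
  attr(z, "labels") <- labs
  attr(z, "seed") <- seed
  z
}

#' Simulate 9-point Likert ratings from a latent space
#'
#' Subject u's rating of sample i on feature j is
#' \code{clip(round(5 + sum_k z[i,k] * W[k,j] + e), 1, 9)} with independent
#' Gaussian noise \code{e ~ N(0, noise_sd^2)} per (subject, sample, feature).
#'
#' @param latent \code{n x D} latent coordinate matrix.
#' @param loadings \code{D x 12} loading matrix (default
#'   \code{\link{default_loading_matrix}}).
#' @param noise_sd Rating noise sd (Likert units).
#' @param n_subjects Number of simulated raters.
#' @param seed RNG seed.
#' @return Integer array \code{n_subjects x n x 12} with values in 1..9.
#' @export
simulate_ratings <- function(latent, loadings = NULL, noise_sd = 1,
                             n_subjects = 58L, seed = 1L) {
  z <- as.matrix(latent)
  D <- ncol(z)
  if (is.null(loadings)) loadings <- default_loading_matrix(D)
  if (nrow(loadings) != D || ncol(loadings) != 12) {
    stop("loadings must be D x 12", call. = FALSE)
  }
  if (n_subjects < 1) stop("n_subjects must be at least 1", call. = FALSE)
  n <- nrow(z)
  mu <- 5 + z %*% loadings  # n x 12
  .with_seed(.hash_seed(seed, "ratings"), {
    out <- array(0L, c(n_subjects, n, 12),
                 dimnames = list(NULL, NULL, colnames(loadings)))
    for (u in seq_len(n_subjects)) {
      r <- round(mu + matrix(stats::rnorm(n * 12, 0, noise_sd), n, 12))
      out[u, , ] <- pmin(9L, pmax(1L, r))
    }
    out
  })
}

# mean pairwise Euclidean distance between two index sets (average linkage)
.group_dist <- function(dmat, a, b) mean(dmat[a, b])

#' Simulate free hierarchical grouping experiments
#'
#' Each simulated subject perceives the latent coordinates through Gaussian
#' perceptual noise, partitions the samples into \code{k_init} initial
#' groups by average-linkage agglomeration on Euclidean distances, repairs
#' singletons by merging each into its nearest group (singletons are not
#' allowed as groups), and then keeps merging the pair of groups with the
#' smallest average-linkage distance until one cluster remains, recording
#' every merge.
#'
#' @param latent \code{n x D} latent coordinate matrix.
#' @param n_subjects Number of simulated subjects (default 20).
#' @param perceptual_noise Gaussian sd of per-subject coordinate noise
#'   (default 0.8, of the order of neighboring model separations).
#' @param k_init Number of initial groups aimed for (default 100: fine
#'   sorters; must satisfy n >= 2 k_init).
#' @param weight_sd Log-normal sd of per-subject axis weights (default
#'   0): each subject attends to the latent axes with their own relative
#'   weights (mean 1), reflecting that individual observers weight
#'   perceptual dimensions differently when judging similarity. The
#'   default 0 keeps subjects metrically identical.
#' @param seed RNG seed.
#' @return List of grouping records, one per subject: list with
#'   \code{subject}, \code{groups} (initial partition; list of integer
#'   vectors, each of size \eqn{\ge} 2) and \code{merges} (ordered list of
#'   pairs of current-group positions; after a merge the joined group
#'   replaces the lower position and the higher position is dropped).
#' @export
simulate_grouping <- function(latent, n_subjects = 20L, perceptual_noise = 0.8,
                              k_init = 100L, weight_sd = 0, seed = 1L) {
  z <- as.matrix(latent)
  n <- nrow(z)
  if (k_init < 2) stop("k_init must be at least 2", call. = FALSE)
  if (2L * k_init > n) {
    stop("k_init too large: need n >= 2 * k_init so that no group is a singleton",
         call. = FALSE)
  }
  lapply(seq_len(n_subjects), function(u) {
    .with_seed(.hash_seed(seed, "grouping", u), {
      w <- exp(stats::rnorm(ncol(z), 0, weight_sd))
      noisy <- sweep(z, 2, w, "*") +
        matrix(stats::rnorm(length(z), 0, perceptual_noise),
               nrow(z), ncol(z))
      dmat <- as.matrix(stats::dist(noisy))
      hc <- stats::hclust(stats::as.dist(dmat), method = "average")
      memb <- stats::cutree(hc, k = k_init)
      groups <- unname(split(seq_len(n), memb))

      # singleton repair: fold each singleton into its nearest group
      repeat {
        sizes <- lengths(groups)
        if (all(sizes >= 2) || length(groups) == 1) break
        s <- which(sizes == 1)[1]
        d <- vapply(seq_along(groups), function(g) {
          if (g == s) Inf else .group_dist(dmat, groups[[s]], groups[[g]])
        }, numeric(1))
        t <- which.min(d)
        a <- min(s, t)
        b <- max(s, t)
        groups[[a]] <- sort(c(groups[[a]], groups[[b]]))
        groups[b] <- NULL
      }
      # stable ordering of the initial partition by first member
      groups <- groups[order(vapply(groups, min, 0L))]
      init <- groups

      # group-level average-linkage distances, maintained by the
      # Lance-Williams update as merges proceed
      g <- length(groups)
      gd <- matrix(0, g, g)
      for (i in seq_len(g)) {
        for (j in seq_len(g)) {
          if (i < j) gd[i, j] <- gd[j, i] <- .group_dist(dmat, groups[[i]],
                                                         groups[[j]])
        }
      }
      sizes <- lengths(groups)
      merges <- list()
      while (length(groups) > 1) {
        dg <- gd
        diag(dg) <- Inf
        best <- which(dg == min(dg), arr.ind = TRUE)
        best <- best[best[, 1] < best[, 2], , drop = FALSE]
        best <- best[order(best[, 1], best[, 2])[1], ]  # lowest index pair
        a <- best[[1]]
        b <- best[[2]]
        merges[[length(merges) + 1]] <- c(a, b)
        newd <- (sizes[a] * gd[a, ] + sizes[b] * gd[b, ]) /
          (sizes[a] + sizes[b])
        gd[a, ] <- newd
        gd[, a] <- newd
        gd[a, a] <- 0
        gd <- gd[-b, -b, drop = FALSE]
        sizes[a] <- sizes[a] + sizes[b]
        sizes <- sizes[-b]
        groups[[a]] <- sort(c(groups[[a]], groups[[b]]))
        groups[b] <- NULL
      }
      list(subject = u, groups = init, merges = merges)
    })
  })
}
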