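# Synthetic observer: planted latent spaces, Likert rating simulation and
# hierarchical grouping records.

tiny_dataset <- function(counts = c(perlin = 6, cellular = 6)) {
  build_dataset(counts, size = 32, master_seed = 3, materialize = FALSE)
}

test_that("planted latent spaces have the designed shape and axis scales", {
  ids <- texture_models()$model_id[1:12]
  ds <- tiny_dataset(stats::setNames(rep(5L, 12), ids))
  z <- plant_latent_space(ds, D = 3, center_scale = c(2.5, 2.0, 1.6),
                          spread = 0.5, seed = 7)
  expect_equal(dim(z), c(60L, 3L))
  # whitened cloud: sample covariance exactly diagonal at the design totals
  cv <- cov(unclass(z)[, 1:3])
  target <- c(2.5, 2.0, 1.6)^2 + 0.5^2
  expect_lt(max(abs(cv - diag(target))), 0.15)  # sweep offset perturbs axis 1
  expect_lt(max(abs(cv[upper.tri(cv)])), 0.1)

  z2 <- plant_latent_space(ds, D = 3, center_scale = c(2.5, 2.0, 1.6),
                           spread = 0.5, seed = 7)
  expect_equal(unclass(z), unclass(z2))  # reproducible per seed
  expect_error(plant_latent_space(list(labels = character(0))), "empty")
})

test_that("models coincide in the spread-to-zero, no-sweep limit", {
  ds <- tiny_dataset(c(perlin = 5, cellular = 5))
  z <- plant_latent_space(ds, D = 2, center_scale = c(2, 2), spread = 1e-9,
                          sweep_amp = 0, seed = 1)
  labs <- attr(z, "labels")
  for (m in unique(labs)) {
    zz <- z[labs == m, , drop = FALSE]
    expect_lt(max(apply(zz, 2, sd)), 1e-6)
  }
})

test_that("model labels are recoverable from the latent geometry", {
  # strong center/spread separation yields high silhouette of model labels
  ds <- tiny_dataset(c(perlin = 10, cellular = 10, wavelet_noise = 10))
  sil <- vapply(1:10, function(s) {
    z <- plant_latent_space(ds, D = 3, center_scale = c(2, 2, 2),
                            spread = 0.4, sweep_amp = 0, seed = s)
    labs <- attr(z, "labels")
    d <- as.matrix(dist(z))
    mean(vapply(seq_len(nrow(z)), function(i) {
      a <- mean(d[i, labs == labs[i] & seq_len(nrow(z)) != i])
      b <- min(vapply(setdiff(unique(labs), labs[i]),
                      function(m) mean(d[i, labs == m]), 0))
      (b - a) / max(a, b)
    }, 0))
  }, 0)
  expect_gte(mean(sil), 0.6)
})

test_that("ratings follow the clipped rounded linear model", {
  ds <- tiny_dataset()
  z <- plant_latent_space(ds, D = 3, seed = 2)
  W0 <- matrix(0, 3, 12)
  r0 <- simulate_ratings(z, W0, noise_sd = 0, n_subjects = 3, seed = 1)
  expect_true(all(r0 == 5))
  expect_equal(dim(r0), c(3L, 12L, 12L))

  # increasing coordinate with positive loading: expected rating non-decreasing
  zl <- cbind(seq(-3, 3, length.out = 30))
  Wp <- matrix(0, 1, 12)
  Wp[1, 4] <- 1
  r <- simulate_ratings(zl, Wp, noise_sd = 0, n_subjects = 1, seed = 1)
  expect_true(all(diff(r[1, , 4]) >= 0))
  expect_true(all(r >= 1 & r <= 9))

  expect_error(simulate_ratings(z, matrix(0, 2, 12)), "D x 12")
})

test_that("subject averaging shrinks rating noise at the expected rate", {
  z <- cbind(rep(0, 40), rep(0, 40), rep(0, 40))
  W <- default_loading_matrix(3)
  r <- simulate_ratings(z, W, noise_sd = 1, n_subjects = 58, seed = 5)
  # single-subject sd is the noise sd (after rounding/clipping); the
  # subject-mean sd should shrink by about 1/sqrt(58)
  single_sd <- sd(r[1, , 1])
  mean_sd <- sd(apply(r[, , 1], 2, mean))
  expect_lt(abs(mean_sd - single_sd / sqrt(58)) / (single_sd / sqrt(58)), 0.35)
})

test_that("grouping records are valid hierarchical histories", {
  set.seed(6)
  lat <- matrix(rnorm(80), 40, 2)
  recs <- simulate_grouping(lat, n_subjects = 4, perceptual_noise = 0.4,
                            k_init = 8, seed = 3)
  expect_length(recs, 4)
  for (rec in recs) {
    expect_equal(sort(unlist(rec$groups)), 1:40)     # exact cover
    expect_true(all(lengths(rec$groups) >= 2))       # no singleton groups
    expect_length(rec$merges, length(rec$groups) - 1)  # full merge history
    # merge indices are valid at each stage
    g <- length(rec$groups)
    for (m in rec$merges) {
      expect_true(m[1] < m[2] && m[2] <= g)
      g <- g - 1
    }
  }
  recs2 <- simulate_grouping(lat, n_subjects = 4, perceptual_noise = 0.4,
                             k_init = 8, seed = 3)
  expect_identical(recs, recs2)
})

test_that("well-separated blobs are grouped identically by noiseless subjects", {
  blobs <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
                 matrix(rnorm(20, 30, 0.05), 10, 2))
  recs <- simulate_grouping(blobs, n_subjects = 3, perceptual_noise = 1e-6,
                            k_init = 2, seed = 1)
  for (rec in recs) {
    expect_length(rec$groups, 2)
    expect_setequal(rec$groups[[which(vapply(rec$groups, function(g)
      1 %in% g, TRUE))]], 1:10)
  }
})

test_that("grouping rejects infeasible initial group counts", {
  lat <- matrix(rnorm(20), 10, 2)
  expect_error(simulate_grouping(lat, 2, 0.1, k_init = 6, seed = 1),
               "k_init too large")
  expect_error(simulate_grouping(lat, 2, 0.1, k_init = 1, seed = 1),
               "at least 2")
})

test_that("the loading matrix encodes the three-axis association pattern", {
  W <- default_loading_matrix(3)
  feats <- feature_schema()$feature
  expect_equal(dim(W), c(3L, 12L))
  expect_setequal(feats[W[1, ] != 0], c("feature_density", "coarseness"))
  expect_setequal(feats[W[2, ] != 0],
                  c("repetition", "randomness", "directionality",
                    "regularity", "local_orientation", "uniformity"))
  expect_lt(W[2, feats == "randomness"], 0)
  expect_setequal(feats[W[3, ] != 0],
                  c("contrast", "granularity", "structural_complexity"))
  expect_true(all(rowSums(W != 0) >= 1))
})
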