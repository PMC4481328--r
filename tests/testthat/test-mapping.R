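# Feature selection, kernel regression onto the space, class merging,
# leave-one-out classification, consistency correlation.

test_that("feature selection thresholds and falls back to top-2", {
  corr <- matrix(0.1, 3, 12)
  corr[1, c(6, 9)] <- c(-0.74, 0.66)
  corr[2, c(2, 4)] <- c(0.8, -0.7)
  corr[3, c(1, 3, 8)] <- 0.5
  sel <- select_axis_features(corr, 0.40)
  expect_equal(sel[[1]], c(6L, 9L))
  expect_equal(sel[[2]], c(2L, 4L))
  expect_equal(sel[[3]], c(1L, 3L, 8L))

  sel_all <- select_axis_features(corr, 0)
  expect_true(all(lengths(sel_all) == 12))

  low <- matrix(0.1, 3, 12)
  low[1, 4] <- 0.3
  low[1, 7] <- 0.25
  low[2, 2] <- 0.9  # axes 2 and 3 qualify; only axis 1 falls back
  low[3, 5] <- 0.9
  expect_warning(sel_low <- select_axis_features(low, 0.4), "top 2")
  expect_equal(sel_low[[1]], c(4L, 7L))
  expect_error(select_axis_features(corr, 1), "threshold")
})

test_that("a noiseless linear chain is recovered almost perfectly", {
  set.seed(31)
  n <- 200
  z <- matrix(rnorm(n * 3), n, 3)
  W <- default_loading_matrix(3)
  Ft <- pmin(pmax(5 + z %*% W, 1), 9)
  coords <- z  # identity mapping: coordinates are the latent axes
  subsets <- planted_feature_sets()
  reg <- fit_axis_regressors(Ft, coords, subsets, cv_folds = 5, seed = 1)
  expect_true(all(reg$report$r_squared >= 0.99))
  expect_true(all(reg$report$mse <= 0.02))
})

test_that("constant targets report zero squared correlation with a warning", {
  set.seed(32)
  Ft <- matrix(runif(60 * 12, 1, 9), 60, 12)
  coords <- cbind(rep(1, 60))
  expect_warning(
    reg <- fit_axis_regressors(Ft, coords, list(1:3), cv_folds = 5, seed = 1),
    "degenerate")
  expect_equal(reg$report$r_squared, 0)
  expect_lt(reg$report$mse, 0.05)
})

test_that("permuted targets carry no held-out signal", {
  set.seed(33)
  n <- 120
  z <- rnorm(n)
  Ft <- matrix(runif(n * 12, 1, 9), n, 12)
  Ft[, 1] <- 5 + z
  r2s <- vapply(1:10, function(s) {
    y <- sample(z)
    reg <- suppressWarnings(
      fit_axis_regressors(Ft, cbind(y), list(1L), cv_folds = 4, seed = s))
    reg$report$r_squared
  }, 0)
  expect_lt(mean(r2s), 0.1)
})

test_that("predictions are consistent between single and batch calls", {
  set.seed(34)
  n <- 80
  z <- matrix(rnorm(n * 3), n, 3)
  Ft <- pmin(pmax(5 + z %*% default_loading_matrix(3), 1), 9)
  reg <- fit_axis_regressors(Ft, z, planted_feature_sets(),
                             cv_folds = 4, seed = 2)
  p1 <- predict_pts(reg, Ft[1, ])
  p2 <- predict_pts(reg, Ft[2, ])
  pb <- predict_pts(reg, Ft[1:2, ])
  expect_equal(pb, rbind(p1, p2))
  # a training row predicts near its (standardized) fitted value
  ctr <- reg$center
  scl <- reg$scale
  expect_lt(max(abs(p1 - (z[1, ] - ctr) / scl)), 0.5)

  expect_error(predict_pts(reg, rep(0, 12)), "within \\[1, 9\\]")
  expect_error(predict_pts(reg, rep(5, 11)), "12 columns")
  expect_error(predict_pts(list(), rep(5, 12)), "fit_axis_regressors")
})

test_that("class merging respects trivial cut levels", {
  set.seed(35)
  S <- matrix(runif(25), 5, 5)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("m", 1:5)
  dn <- hca_dendrogram(S)
  cm0 <- merge_model_classes(dn, 0)
  expect_equal(length(unique(cm0)), 5)
  cm1 <- merge_model_classes(dn, max(dn$hclust$height) + 1)
  expect_equal(length(unique(cm1)), 1)
  cmr <- merge_model_classes(dn, 0.5, relative = TRUE)
  expect_equal(cmr, cut_dendrogram(dn, 0.5 * max(dn$hclust$height)))
})

test_that("leave-one-out classification separates well-separated classes", {
  set.seed(36)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 8, 0.2), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  res <- loo_classify(x, y, seed = 1)
  expect_equal(res$accuracy, 1.0)
  expect_equal(dim(res$confusion), c(2L, 2L))
})

test_that("shuffled labels classify at chance level", {
  set.seed(37)
  n <- 100
  x <- matrix(rnorm(n * 2), n, 2)
  y <- sample(rep(letters[1:5], each = 20))
  res <- loo_classify(x, y, seed = 2)
  # 99% binomial band around 0.2 with n = 100
  band <- qbinom(c(0.005, 0.995), n, 0.2) / n
  expect_gte(res$accuracy, band[1])
  expect_lte(res$accuracy, band[2])
})

test_that("singleton classes are flagged", {
  set.seed(38)
  x <- matrix(rnorm(22), 11, 2)
  y <- c(rep("a", 5), rep("b", 5), "c")
  expect_warning(res <- loo_classify(x, y, seed = 1), "singleton")
  expect_equal(res$singleton_classes, "c")
})

test_that("consistency correlation is exact for affine relations and null otherwise", {
  set.seed(39)
  X <- matrix(rnorm(60), 20, 3)
  Dm <- as.matrix(dist(X))
  S <- 1 - Dm / max(Dm)  # distances an exact affine decreasing function
  expect_equal(consistency_correlation(S, X), 1, tolerance = 1e-12)

  rs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    S2 <- matrix(runif(100 * 100), 100, 100)
    S2 <- (S2 + t(S2)) / 2
    diag(S2) <- 1
    consistency_correlation(S2, matrix(rnorm(300), 100, 3))
  }, 0)
  expect_lt(mean(rs), 0.1)

  expect_error(consistency_correlation(S, matrix(1, 20, 2)), "constant")
})

test_that("axis matching recovers permutations of a clean correlation table", {
  sets <- planted_feature_sets()
  corr <- matrix(0.05, 3, 12)
  corr[2, sets[[1]]] <- 0.8   # recovered axis 2 is planted axis 1
  corr[3, sets[[2]]] <- -0.7
  corr[1, sets[[3]]] <- 0.75
  perm <- texspace:::.match_axes(corr, sets)
  expect_equal(perm, c(2L, 3L, 1L))
})
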