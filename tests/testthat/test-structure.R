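# Dendrogram construction/cutting and the truncated-SVD biplot.

random_model_similarity <- function(m) {
  S <- matrix(runif(m * m), m, m)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("m", seq_len(m))
  S
}

test_that("identical similarity rows merge first at height zero", {
  S <- random_model_similarity(5)
  S[2, ] <- S[1, ]
  S[, 2] <- S[, 1]
  S[1, 2] <- S[2, 1] <- S[1, 1]
  dn <- hca_dendrogram(S)
  expect_equal(dn$hclust$height[1], 0)
  expect_setequal(abs(dn$hclust$merge[1, ]), c(1, 2))
})

test_that("merge history matches exhaustive average-linkage enumeration", {
  set.seed(11)
  for (rep in 1:10) {
    m <- sample(4:6, 1)
    S <- random_model_similarity(m)
    dn <- hca_dendrogram(S)
    oracle <- oracle_average_linkage(as.matrix(dist(S)))
    got <- hclust_merge_sets(dn$hclust)
    expect_equal(dn$hclust$height, oracle$heights, tolerance = 1e-12)
    for (s in seq_along(got)) {
      pair_got <- list(got[[s]]$a, got[[s]]$b)
      pair_exp <- list(oracle$merges[[s]]$a, oracle$merges[[s]]$b)
      expect_true(setequal(pair_got[[1]], pair_exp[[1]]) &&
                    setequal(pair_got[[2]], pair_exp[[2]]) ||
                  setequal(pair_got[[1]], pair_exp[[2]]) &&
                    setequal(pair_got[[2]], pair_exp[[1]]))
    }
  }
})

test_that("merge heights are non-decreasing", {
  set.seed(5)
  for (rep in 1:5) {
    S <- random_model_similarity(8)
    h <- hca_dendrogram(S)$hclust$height
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("dendrogram input validation rejects malformed matrices", {
  expect_error(hca_dendrogram(matrix(1, 2, 3)), "square")
  A <- matrix(c(1, 0.5, 0.1, 1), 2, 2)
  expect_error(hca_dendrogram(A), "symmetric")
})

test_that("cut levels reproduce the trivial partitions and are monotone", {
  set.seed(2)
  S <- random_model_similarity(7)
  dn <- hca_dendrogram(S)
  expect_equal(length(unique(cut_dendrogram(dn, 0))), 7)
  expect_equal(length(unique(cut_dendrogram(dn, Inf))), 1)
  levels <- seq(0, max(dn$hclust$height) * 1.1, length.out = 12)
  sizes <- vapply(levels, function(l) length(unique(cut_dendrogram(dn, l))), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("rank-deficient inputs yield exact truncated reconstructions", {
  set.seed(8)
  u <- runif(6)
  v <- runif(12)
  F1 <- outer(u, v)  # rank 1
  sv <- svd_embed(F1)
  expect_gt(sv$Sigma3[1], 0)
  expect_lt(sv$Sigma3[2] / sv$Sigma3[1], 1e-12)

  F3 <- outer(runif(8), runif(12)) + outer(runif(8), runif(12)) +
    outer(runif(8), runif(12))  # rank 3
  sv3 <- svd_embed(F3)
  rec <- sv3$U3 %*% diag(sv3$Sigma3) %*% t(sv3$V3)
  expect_lt(max(abs(rec - F3)), 1e-10)
  expect_lt(max(abs(t(rec) - t(F3))), 1e-10)  # feature-by-model transpose
})

test_that("singular vectors are orthonormal and ordered", {
  set.seed(9)
  Fm <- matrix(runif(10 * 12, 1, 9), 10, 12)
  sv <- svd_embed(Fm)
  expect_lt(max(abs(crossprod(sv$U3) - diag(3))), 1e-10)
  expect_lt(max(abs(crossprod(sv$V3) - diag(3))), 1e-10)
  expect_true(all(diff(sv$Sigma3) <= 0))
  # Frobenius error of the rank-3 truncation equals the tail singular mass
  rec <- sv$U3 %*% diag(sv$Sigma3) %*% t(sv$V3)
  full <- svd(Fm)
  expect_equal(sqrt(sum((Fm - rec)^2)),
               sqrt(sum(full$d[-(1:3)]^2)), tolerance = 1e-10)
})

test_that("biplot takes columns 2 and 3 verbatim and ignores sign flips", {
  set.seed(10)
  Fm <- matrix(runif(9 * 12, 1, 9), 9, 12,
               dimnames = list(paste0("m", 1:9), feature_schema()$feature))
  sv <- svd_embed(Fm)
  b <- biplot_coordinates(sv)
  expect_equal(unname(b$models), unname(sv$U3[, 2:3]))
  expect_equal(unname(b$features), unname(sv$V3[, 2:3]))
  expect_equal(nrow(b$models), 9)
  expect_equal(nrow(b$features), 12)

  # flipping the sign of a singular-vector pair preserves all distances
  sv2 <- sv
  sv2$U3[, 2] <- -sv2$U3[, 2]
  sv2$V3[, 2] <- -sv2$V3[, 2]
  b2 <- biplot_coordinates(sv2)
  all_pts <- rbind(b$models, b$features)
  all_pts2 <- rbind(b2$models, b2$features)
  expect_equal(as.matrix(dist(all_pts)), as.matrix(dist(all_pts2)),
               tolerance = 1e-12)
})

test_that("a model loading on a single feature sits nearest that feature", {
  # rank-2 construction: model rows are indicator-like profiles so model A
  # aligns with feature 3 in the biplot plane
  base <- matrix(1, 6, 12)
  Fm <- base
  Fm[1, 3] <- 8   # model A strongly expresses feature 3
  Fm[2:6, 7] <- 4 # the rest express feature 7
  rownames(Fm) <- paste0("m", 1:6)
  colnames(Fm) <- feature_schema()$feature
  b <- biplot_coordinates(svd_embed(Fm))
  d_to_f3 <- sqrt(rowSums(sweep(b$models, 2, b$features[3, ])^2))
  expect_equal(which.min(d_to_f3), 1L, ignore_attr = TRUE)
})
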