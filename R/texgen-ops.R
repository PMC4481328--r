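# Post-processing operator families: Folding (triangle fold of a base
# field) and Fusion (convex blend of two base fields). The base fields are
# produced by the corresponding primitive generators using the already-seeded
# RNG stream, so composites remain deterministic per seed.

.minmax01 <- function(m) {
  rng <- range(m)
  if (!all(is.finite(rng)) || rng[2] - rng[1] < .Machine$double.eps) {
    return(matrix(0.5, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

# Triangle fold |2x - 1| applied `fold` times to the min-max-normalized base
# field; repeated folding creates marble-like banding.
.fold_field <- function(base, fold) {
  x <- .minmax01(base)
  for (k in seq_len(max(1L, as.integer(round(fold))))) {
    x <- abs(2 * x - 1)
  }
  x
}

.gen_folding_texton <- function(size, values) {
  base <- .gen_texton_random_grid(size, c(spacing = values[["spacing"]]))
  .fold_field(base, values[["fold"]])
}

.gen_folding_cellular <- function(size, values) {
  base <- .gen_cellular(size, c(n_features = values[["n_features"]], shape = 0))
  .fold_field(base, values[["fold"]])
}

.gen_folding_fractal <- function(size, values) {
  base <- .gen_fractal_fourier(size, c(beta = values[["beta"]]))
  .fold_field(base, values[["fold"]])
}

.gen_folding_perlin <- function(size, values) {
  base <- .gen_perlin(size, c(frequency = values[["frequency"]]))
  .fold_field(base, values[["fold"]])
}

# Fusion: w * X + (1 - w) * Y on min-max-normalized base fields.
.fuse <- function(a, b, w) w * .minmax01(a) + (1 - w) * .minmax01(b)

.gen_fusion_cellular_texton <- function(size, values) {
  a <- .gen_cellular(size, c(n_features = 30, shape = 0))
  b <- .gen_texton_random_grid(size, c(spacing = max(8, size %/% 8)))
  .fuse(a, b, values[["weight"]])
}

.gen_fusion_perlin_cellular <- function(size, values) {
  a <- .gen_perlin(size, c(frequency = 6))
  b <- .gen_cellular(size, c(n_features = 30, shape = 0))
  .fuse(a, b, values[["weight"]])
}

.gen_fusion_perlin_texton <- function(size, values) {
  a <- .gen_perlin(size, c(frequency = 6))
  b <- .gen_texton_random_grid(size, c(spacing = max(8, size %/% 8)))
  .fuse(a, b, values[["weight"]])
}
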