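# Procedural generator contracts: determinism, normalization, sweep
# conventions, dataset assembly, and the structural sanity of individual
# model families.

test_that("generation is deterministic and normalized for every model", {
  for (id in texture_models()$model_id) {
    ps <- parameter_sweep(id, 2, master_seed = 7)[[1]]
    a <- generate_height_map(ps, 32)
    b <- generate_height_map(ps, 32)
    expect_identical(a$heights, b$heights)
    expect_equal(min(a$heights), 0)
    expect_equal(max(a$heights), 1)
    expect_true(all(is.finite(a$heights)))
  }
})

test_that("distinct sweep positions produce visibly different grids", {
  # at least 1% of pixels must differ between the sweep endpoints
  for (id in c("perlin", "cellular", "ca_surface_tension", "texton_regular",
               "fractal_fourier", "matrix_transformation")) {
    sw <- parameter_sweep(id, 3, master_seed = 3)
    a <- generate_height_map(sw[[1]], 48)$heights
    b <- generate_height_map(sw[[3]], 48)$heights
    expect_gt(mean(abs(a - b) > 1e-9), 0.01)
  }
})

test_that("parameter sweeps are linear with endpoint and midpoint conventions", {
  sw <- parameter_sweep("fractal_fourier", 3)
  betas <- vapply(sw, function(p) p$values[["beta"]], 0)
  expect_equal(betas, c(0, 1.5, 3))

  sw1 <- parameter_sweep("perlin", 1)
  expect_equal(sw1[[1]]$values[["frequency"]], 7)  # midpoint of [2, 12]

  expect_error(parameter_sweep("perlin", 0), "at least 1")
  expect_error(parameter_sweep("nosuchmodel", 3), "unknown model_id")
})

test_that("per-sample seeds derive deterministically from the master seed", {
  s1 <- parameter_sweep("cellular", 4, master_seed = 11)
  s2 <- parameter_sweep("cellular", 4, master_seed = 11)
  s3 <- parameter_sweep("cellular", 4, master_seed = 12)
  expect_identical(vapply(s1, `[[`, 0L, "seed"), vapply(s2, `[[`, 0L, "seed"))
  expect_false(any(vapply(s1, `[[`, 0L, "seed") ==
                     vapply(s3, `[[`, 0L, "seed")))
})

test_that("parameter sets validate ranges and model ids", {
  expect_error(param_set("perlin", c(frequency = 99)), "outside declared range")
  expect_error(param_set("perlin", c(wrong = 1)), "missing parameter")
  expect_error(param_set("bogus", c(x = 1)), "unknown model_id")
  expect_error(generate_height_map(param_set("perlin", c(frequency = 4)), 8),
               "at least 16")
  expect_error(
    generate_height_map(param_set("texton_regular", c(spacing = 40)), 32),
    "smaller than the image size")
})

test_that("dataset assembly follows registry order and emits count warnings", {
  ds <- build_dataset(c(cellular = 2, perlin = 3), size = 32, master_seed = 1)
  expect_length(ds$samples, 5)
  expect_equal(ds$labels, c(rep("cellular", 2), rep("perlin", 3)))
  expect_equal(length(ds$manifest), 5)

  expect_warning(
    build_dataset(c(perlin = 1, cellular = 2), size = 32, materialize = FALSE),
    "single sample")
  expect_error(build_dataset(c(perlin = 3), size = 32), "at least 2 models")
  expect_error(build_dataset(c(perlin = 3, bogus = 2), size = 32),
               "unknown model_id")
  expect_error(build_dataset(integer(0)), "empty")
})

test_that("default configuration totals 450 samples over 23 models", {
  counts <- default_model_counts()
  expect_length(counts, 23)
  expect_equal(sum(counts), 450)
  ds <- build_dataset(counts, size = 64, materialize = FALSE)
  expect_length(ds$labels, 450)
  expect_equal(length(unique(ds$labels)), 23)
})

test_that("datasets are reproducible byte-for-byte from (config, seed)", {
  cfg <- c(perlin = 2, wavelet_noise = 2)
  d1 <- build_dataset(cfg, size = 32, master_seed = 5)
  d2 <- build_dataset(cfg, size = 32, master_seed = 5)
  expect_identical(lapply(d1$samples, `[[`, "heights"),
                   lapply(d2$samples, `[[`, "heights"))
})

test_that("regular texton grids put autocorrelation peaks at the stamp spacing", {
  hm <- generate_height_map(param_set("texton_regular", c(spacing = 32), 4),
                            256)$heights
  x <- hm - mean(hm)
  # circular autocorrelation via the Wiener-Khinchin theorem
  ac <- Re(fft(Mod(fft(x))^2, inverse = TRUE))
  ac <- ac / ac[1, 1]
  # peaks at all lags that are multiples of the spacing
  on_lag <- ac[1 + seq(32, 224, by = 32), 1]
  off_lag <- ac[1 + seq(16, 240, by = 32), 1]
  expect_true(min(on_lag) > max(off_lag))
  expect_gt(min(on_lag), 0.5)
})

test_that("cellular automata conserve their state alphabets at every step", {
  states <- withr::with_seed(1, texspace:::.gen_ca_forest_fire(
    32, c(p_grow = 0.3), history = TRUE))
  for (s in states) expect_true(all(s %in% c(0, 1, 2)))

  r <- 4
  states <- withr::with_seed(1, texspace:::.gen_ca_excitable(
    32, c(refractory = r), history = TRUE))
  for (s in states) expect_true(all(s %in% 0:(r + 1)))
})

test_that("spectral synthesis at beta = 0 has a flat radial spectrum", {
  size <- 64
  acc <- matrix(0, size, size)
  for (seed in 1:20) {
    hm <- generate_height_map(
      param_set("fractal_fourier", c(beta = 0), seed), size)$heights
    x <- hm - mean(hm)
    acc <- acc + Mod(fft(x))^2
  }
  f <- texspace:::.freq_grid(size)$fr
  bins <- cut(f[f > 0 & f <= size / 2], breaks = seq(0.5, size / 2, by = 3))
  pw <- tapply(acc[f > 0 & f <= size / 2], bins, mean)
  pw <- pw[!is.na(pw)]
  # flat within sampling error: all radial bins close to the common mean
  expect_lt(max(pw) / min(pw), 1.35)
  # and the log-log slope is near zero
  mids <- seq_along(pw)
  fit <- stats::lm(log(pw) ~ log(mids))
  expect_lt(abs(stats::coef(fit)[2]), 0.06)
})

test_that("non-flat spectral synthesis concentrates power at low frequencies", {
  size <- 64
  hm <- generate_height_map(param_set("fractal_fourier", c(beta = 2.5), 1),
                            size)$heights
  x <- hm - mean(hm)
  p <- Mod(fft(x))^2
  f <- texspace:::.freq_grid(size)$fr
  low <- mean(p[f > 0 & f <= 4])
  high <- mean(p[f >= 16 & f <= 32])
  expect_gt(low / high, 50)
})
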