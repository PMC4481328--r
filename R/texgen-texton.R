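# Texton placement/addition generators and the two deterministic structured
# families (fabric weave, star-motif wallpaper). Stamping is toroidal: an
# impulse field is convolved with the stamp kernel in the Fourier domain, so
# every stamp wraps around the image borders.

# Toroidally centered stamp kernel: smooth radial bump of radius r at the
# origin of an n x n grid.
.stamp_kernel <- function(n, r) {
  xs <- 0:(n - 1)
  d1 <- pmin(xs, n - xs)
  d2 <- sqrt(outer(d1^2, d1^2, "+"))
  k <- 1 - (d2 / r)^2
  k[k < 0] <- 0
  k
}

# Convolve an impulse field with a kernel on the torus.
.conv_torus <- function(imp, kern) {
  n <- nrow(imp)
  Re(stats::fft(stats::fft(imp) * stats::fft(kern), inverse = TRUE)) / (n * n)
}

# Stamp unit textons at integer pixel positions (0-based, wrapped).
# `combine = "place"` clips overlaps at one stamp height; "add" keeps sums.
.stamp_at <- function(size, px, py, radius, combine = c("place", "add")) {
  combine <- match.arg(combine)
  imp <- matrix(0, size, size)
  ii <- (round(py) %% size) + 1
  jj <- (round(px) %% size) + 1
  for (k in seq_along(ii)) imp[ii[k], jj[k]] <- imp[ii[k], jj[k]] + 1
  out <- .conv_torus(imp, .stamp_kernel(size, radius))
  if (combine == "place") out <- pmin(out, 1)
  out
}

.gen_texton_regular <- function(size, values) {
  s <- max(4L, as.integer(round(values[["spacing"]])))
  pos <- seq(0, size - 1, by = s)
  g <- expand.grid(px = pos, py = pos)
  .stamp_at(size, g$px, g$py, radius = max(2, 0.3 * s), combine = "place")
}

# Jittered grid ("random grid"): regular grid positions with uniform jitter.
.gen_texton_random_grid <- function(size, values) {
  s <- max(4L, as.integer(round(values[["spacing"]])))
  pos <- seq(0, size - 1, by = s)
  g <- expand.grid(px = pos, py = pos)
  jit <- 0.35 * s
  px <- g$px + stats::runif(nrow(g), -jit, jit)
  py <- g$py + stats::runif(nrow(g), -jit, jit)
  .stamp_at(size, px, py, radius = max(2, 0.3 * s), combine = "place")
}

.gen_texton_random_walk <- function(size, values) {
  nsteps <- max(10L, as.integer(round(values[["n_steps"]])))
  rad <- max(2, size / 24)
  step <- rad * 1.2
  ang <- stats::runif(1, 0, 2 * pi)
  px <- numeric(nsteps)
  py <- numeric(nsteps)
  x <- stats::runif(1, 0, size)
  y <- stats::runif(1, 0, size)
  for (k in seq_len(nsteps)) {
    ang <- ang + stats::rnorm(1, 0, 0.8)
    x <- (x + step * cos(ang)) %% size
    y <- (y + step * sin(ang)) %% size
    px[k] <- x
    py[k] <- y
  }
  .stamp_at(size, px, py, radius = rad, combine = "place")
}

# Uniform-random placement modulated by a smooth probability map (low-pass
# random-phase noise rescaled to [0.05, 1]); candidates are accepted by
# rejection sampling against the map.
.gen_texton_probability_map <- function(size, values) {
  npts <- max(10L, as.integer(round(values[["n_points"]])))
  pm <- .gen_fractal_fourier(size, c(beta = 2.5))
  pm <- (pm - min(pm)) / max(max(pm) - min(pm), .Machine$double.eps)
  pm <- 0.05 + 0.95 * pm
  ncand <- npts * 3L
  cx <- stats::runif(ncand, 0, size)
  cy <- stats::runif(ncand, 0, size)
  pr <- pm[cbind(floor(cy) + 1, floor(cx) + 1)]
  keep <- stats::runif(ncand) < pr
  .stamp_at(size, cx[keep], cy[keep], radius = max(2, size / 24), combine = "place")
}

# Summed overlapping stamps ("texton addition").
.gen_texton_addition <- function(size, values) {
  rad <- max(2, values[["radius"]] * size / 64)
  npts <- as.integer(round(0.004 * size * size))
  px <- stats::runif(npts, 0, size)
  py <- stats::runif(npts, 0, size)
  .stamp_at(size, px, py, radius = rad, combine = "add")
}

# Fabric-weave pattern: interleaved orthogonal sinusoid gratings in a
# checkerboard of threads. Deterministic given the thread frequency.
.gen_matrix_transformation <- function(size, values) {
  f <- max(2L, as.integer(round(values[["frequency"]])))
  t1 <- (0:(size - 1)) / size
  warp <- sin(2 * pi * f * t1)^2          # varies along x
  weft <- sin(2 * pi * f * t1)^2          # varies along y
  W <- matrix(warp, size, size, byrow = TRUE)
  F2 <- matrix(weft, size, size)
  cell <- outer(floor(t1 * f), floor(t1 * f), "+") %% 2  # rows=y, cols=x
  cell * W + (1 - cell) * F2
}

# Star-motif wallpaper: one random k-pointed star in a tile, symmetrized by
# horizontal/vertical reflection, then replicated 2 x 2.
.gen_islamic_patterns <- function(size, values) {
  k <- max(3L, as.integer(round(values[["n_points"]])))
  tl <- size %/% 2
  cx <- (tl + 1) / 2
  xs <- seq_len(tl) - cx
  X <- matrix(xs, tl, tl, byrow = TRUE)
  Y <- matrix(xs, tl, tl)
  r <- sqrt(X^2 + Y^2) / (tl / 2)
  th <- atan2(Y, X)
  phi <- stats::runif(1, 0, 2 * pi)
  edge <- 0.55 * (1 + 0.45 * cos(k * th + phi))
  w <- 0.08
  star <- pmin(pmax((edge - r) / w, 0), 1)
  ring <- pmin(pmax((r - 0.75) / w, 0), 1) * pmin(pmax((0.95 - r) / w, 0), 1)
  tile <- pmax(star, 0.6 * ring)
  tile <- (tile + tile[, rev(seq_len(tl))] + tile[rev(seq_len(tl)), ] +
             tile[rev(seq_len(tl)), rev(seq_len(tl))]) / 4
  big <- rbind(cbind(tile, tile), cbind(tile, tile))
  if (nrow(big) < size) {
    # odd sizes: pad by wrapping
    idx <- ((0:(size - 1)) %% nrow(big)) + 1
    big <- big[idx, idx]
  }
  big[seq_len(size), seq_len(size)]
}
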