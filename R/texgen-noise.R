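# Noise-family height-map generators. All generators take (size, values) with
# the RNG already seeded by generate_height_map(), and return an un-normalized
# numeric matrix (rows = y, columns = x).

# FFT frequency coordinate along one axis, in cycles per image.
.fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

# Radial frequency grid |f| in cycles per image (rows = fy, cols = fx).
.freq_grid <- function(n) {
  f <- .fft_freqs(n)
  fy <- matrix(f, n, n)
  fx <- matrix(f, n, n, byrow = TRUE)
  list(fx = fx, fy = fy, fr = sqrt(fx^2 + fy^2))
}

# Shape white Gaussian noise with a Fourier-amplitude envelope. The white
# field's transform supplies random phases (and Rayleigh amplitudes); the
# envelope fixes the expected power spectrum proportional to amp^2.
.spectral_noise <- function(size, amp) {
  white <- matrix(stats::rnorm(size * size), size, size)
  f <- stats::fft(white) * amp
  Re(stats::fft(f, inverse = TRUE)) / (size * size)
}

# Quintic fade 6t^5 - 15t^4 + 10t^3 (C2-continuous at lattice points).
.fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)

# Classic Perlin gradient noise on an n x n toroidal lattice of unit
# gradients; `frequency` is the number of lattice cells across the image.
.gen_perlin <- function(size, values) {
  n <- max(2L, as.integer(round(values[["frequency"]])))
  ang <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
  gx <- cos(ang)
  gy <- sin(ang)

  t1 <- (0:(size - 1)) / size * n
  i0 <- floor(t1)
  fr <- t1 - i0
  i0 <- i0 %% n
  i1 <- (i0 + 1) %% n

  # column-major lookup into the n x n gradient tables
  IX0 <- matrix(i0, size, size, byrow = TRUE)
  IX1 <- matrix(i1, size, size, byrow = TRUE)
  IY0 <- matrix(i0, size, size)
  IY1 <- matrix(i1, size, size)
  FX <- matrix(fr, size, size, byrow = TRUE)
  FY <- matrix(fr, size, size)

  idx00 <- IY0 + n * IX0 + 1
  idx10 <- IY0 + n * IX1 + 1
  idx01 <- IY1 + n * IX0 + 1
  idx11 <- IY1 + n * IX1 + 1

  d00 <- gx[idx00] * FX + gy[idx00] * FY
  d10 <- gx[idx10] * (FX - 1) + gy[idx10] * FY
  d01 <- gx[idx01] * FX + gy[idx01] * (FY - 1)
  d11 <- gx[idx11] * (FX - 1) + gy[idx11] * (FY - 1)

  u <- .fade(FX)
  v <- .fade(FY)
  nx0 <- d00 + u * (d10 - d00)
  nx1 <- d01 + u * (d11 - d01)
  nx0 + v * (nx1 - nx0)
}

# Wavelet-style noise: a sum of band-limited noise bands, each an octave
# apart, realized as log-frequency Gaussian annuli in the Fourier domain.
.gen_wavelet <- function(size, values) {
  nb <- max(2L, as.integer(round(values[["n_bands"]])))
  nyq <- size / 2
  g <- .freq_grid(size)
  amp <- matrix(0, size, size)
  for (b in seq_len(nb)) {
    fc <- nyq / 2^b
    w <- 0.6^(nb - b)  # lower-frequency bands weighted up
    band <- exp(-(log2(pmax(g$fr, 1e-9) / fc))^2 / (2 * 0.5^2))
    amp <- amp + w * band
  }
  amp[1, 1] <- 0
  .spectral_noise(size, amp)
}

# Fourier spectral synthesis: random-phase spectrum with amplitude 1/f^beta.
# beta = 0 reduces to white noise (flat expected spectrum).
.gen_fractal_fourier <- function(size, values) {
  beta <- values[["beta"]]
  g <- .freq_grid(size)
  amp <- ifelse(g$fr > 0, g$fr^(-beta), 0)
  amp[1, 1] <- 0
  .spectral_noise(size, amp)
}

# Axis-anisotropic one-over-f-beta noise: the vertical frequency axis is
# attenuated, concentrating energy in horizontal frequencies and producing
# the characteristic vertically striped regime.
.gen_fractal_1overf <- function(size, values) {
  beta <- values[["beta"]]
  aniso <- 4
  g <- .freq_grid(size)
  fe <- sqrt(g$fx^2 + (aniso * g$fy)^2)
  amp <- ifelse(fe > 0, fe^(-beta), 0)
  amp[1, 1] <- 0
  .spectral_noise(size, amp)
}
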