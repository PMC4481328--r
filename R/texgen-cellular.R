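# Cellular-automaton and cellular (nearest-feature) height-map generators.
# Toroidal neighborhoods throughout, so no border artifacts.

# Toroidal shift of a matrix by (di, dj) (rows down, columns right).
.shift <- function(m, di, dj) {
  n <- nrow(m)
  p <- ncol(m)
  ri <- ((seq_len(n) - 1 - di) %% n) + 1
  cj <- ((seq_len(p) - 1 - dj) %% p) + 1
  m[ri, cj, drop = FALSE]
}

# Number of 8-neighbors (Moore) with a given state.
.moore_count <- function(ind) {
  .shift(ind, 1, 0) + .shift(ind, -1, 0) + .shift(ind, 0, 1) + .shift(ind, 0, -1) +
    .shift(ind, 1, 1) + .shift(ind, 1, -1) + .shift(ind, -1, 1) + .shift(ind, -1, -1)
}

.vn_count <- function(ind) {
  .shift(ind, 1, 0) + .shift(ind, -1, 0) + .shift(ind, 0, 1) + .shift(ind, 0, -1)
}

# Cellular texture (Worley): distance to nearest feature points on a torus.
# `shape` interpolates between the F1 field and the F2 - F1 field.
.gen_cellular <- function(size, values) {
  npts <- max(4L, as.integer(round(values[["n_features"]])))
  shape <- if ("shape" %in% names(values)) values[["shape"]] else 0
  px <- stats::runif(npts) * size
  py <- stats::runif(npts) * size
  xs <- 0:(size - 1)
  out_f1 <- matrix(Inf, size, size)
  out_f2 <- matrix(Inf, size, size)
  # accumulate per feature point; toroidal axis distances
  for (k in seq_len(npts)) {
    dx <- abs(xs - px[k])
    dx <- pmin(dx, size - dx)
    dy <- abs(xs - py[k])
    dy <- pmin(dy, size - dy)
    d <- sqrt(outer(dy^2, dx^2, "+"))
    new_f1 <- pmin(out_f1, d)
    out_f2 <- pmin(out_f2, pmax(out_f1, d))
    out_f1 <- new_f1
  }
  (1 - shape) * out_f1 + shape * (out_f2 - out_f1)
}

# Drossel-Schwabl forest-fire automaton. States: 0 empty, 1 tree, 2 burning.
# Returns the final state field (trees high, burning mid, empty low); with
# history = TRUE returns the list of state matrices for inspection.
.gen_ca_forest_fire <- function(size, values, history = FALSE) {
  p_grow <- values[["p_grow"]]
  f_ignite <- 0.002
  steps <- 64L
  state <- matrix(ifelse(stats::runif(size * size) < 0.3, 1, 0), size, size)
  states <- if (history) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    burning <- (state == 2) * 1
    tree <- state == 1
    nb <- .moore_count(burning)
    new <- state
    new[state == 2] <- 0
    catch <- tree & (nb > 0 | stats::runif(size * size) < f_ignite)
    new[catch] <- 2
    grow <- (state == 0) & (stats::runif(size * size) < p_grow)
    new[grow] <- 1
    state <- new
    if (history) states[[s]] <- state
  }
  if (history) return(states)
  # trees read as raised relief, burning mid-level, empty ground low
  state_map <- c(0, 1, 0.5)
  matrix(state_map[state + 1], size, size)
}

# Surface-tension automaton: iterated local-majority smoothing of a random
# binary field; blobs round off like droplets under surface tension.
.gen_ca_surface_tension <- function(size, values) {
  dens <- values[["density"]]
  iters <- 24L
  state <- matrix(ifelse(stats::runif(size * size) < dens, 1, 0), size, size)
  for (s in seq_len(iters)) {
    tot <- .moore_count(state) + state
    state <- (tot >= 5) * 1
  }
  state
}

# Greenberg-Hastings excitable medium. States: 0 resting, 1 excited,
# 2..(r+1) refractory countdown. Produces spiral/target wave fields.
.gen_ca_excitable <- function(size, values, history = FALSE) {
  r <- max(2L, as.integer(round(values[["refractory"]])))
  steps <- 48L
  nstate <- r + 2L
  state <- matrix(sample(0:(nstate - 1), size * size, replace = TRUE,
                         prob = c(0.85, 0.05, rep(0.10 / r, r))),
                  size, size)
  states <- if (history) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    excited <- (state == 1) * 1
    nb <- .vn_count(excited)
    new <- state
    new[state == 0 & nb > 0] <- 1
    adv <- state >= 1
    new[adv] <- (state[adv] + 1) %% nstate
    # excited cells advance to first refractory state regardless
    new[state == 1] <- 2 %% nstate
    state <- new
    if (history) states[[s]] <- state
  }
  if (history) return(states)
  state / (nstate - 1)
}

# Gray-Scott reaction-diffusion integrated to a quasi-steady state; the
# feed rate sweeps through spot/stripe/labyrinth regimes.
.gen_reaction_diffusion <- function(size, values) {
  feed <- values[["feed"]]
  kill <- 0.061
  du <- 0.16
  dv <- 0.08
  steps <- 2500L
  u <- matrix(1, size, size)
  v <- matrix(0, size, size)
  # seed random square perturbations, more on larger grids
  nseed <- max(4L, size %/% 8L)
  w <- 4L
  for (k in seq_len(nseed)) {
    i <- sample.int(size - w, 1)
    j <- sample.int(size - w, 1)
    u[i:(i + w), j:(j + w)] <- 0.50
    v[i:(i + w), j:(j + w)] <- 0.25
  }
  u <- u + 0.02 * matrix(stats::runif(size * size), size, size)
  lap <- function(m) {
    .vn_count(m) - 4 * m
  }
  for (s in seq_len(steps)) {
    uvv <- u * v * v
    u <- u + du * lap(u) - uvv + feed * (1 - u)
    v <- v + dv * lap(v) + uvv - (feed + kill) * v
  }
  v
}
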