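# Deterministic seed fan-out. All randomness in the package flows from a
# single master seed through a splitmix-style 32-bit mixer, so that per-sample
# and per-stage streams are stable across platforms and independent of the
# order in which stages run.

# 32-bit modular product using 16-bit limbs; exact in double precision.
.mul32 <- function(a, b) {
  a <- a %% 4294967296
  b <- b %% 4294967296
  alo <- a %% 65536
  ahi <- (a - alo) / 65536
  blo <- b %% 65536
  bhi <- (b - blo) / 65536
  lo <- alo * blo
  mid <- (alo * bhi + ahi * blo) %% 65536
  (lo + mid * 65536) %% 4294967296
}

# xor of two 32-bit values held as doubles
.xor32 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    da <- a %% 2
    db <- b %% 2
    if (da != db) r <- r + p
    a <- (a - da) / 2
    b <- (b - db) / 2
    p <- p * 2
  }
  r
}

# splitmix32 finalizer: avalanche a 32-bit state held as a double.
.splitmix32 <- function(x) {
  x <- (x + 2654435769) %% 4294967296  # golden-ratio increment
  z <- x
  z <- .xor32(z, floor(z / 65536))             # z ^= z >> 16
  z <- .mul32(z, 2246822507)                   # 0x85EBCA6B
  z <- .xor32(z, floor(z / 8192))              # z ^= z >> 13
  z <- .mul32(z, 3266489909)                   # 0xC2B2AE35
  z <- .xor32(z, floor(z / 65536))             # z ^= z >> 16
  z
}

# Hash an arbitrary mix of strings/numbers into a seed usable by set.seed().
# Stable: depends only on the byte content of the arguments.
.hash_seed <- function(...) {
  parts <- list(...)
  h <- 0
  for (p in parts) {
    if (is.character(p)) {
      for (b in utf8ToInt(paste(p, collapse = "\x1f"))) {
        h <- .splitmix32(h + b)
      }
    } else {
      for (v in as.numeric(p)) {
        h <- .splitmix32(h + (v %% 4294967296))
      }
    }
  }
  as.integer(h %% 2147483647)
}

# Run an expression under a local RNG state seeded from parts, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
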