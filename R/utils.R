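# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic operations in the package
# go through this so that per-stage seeds fully determine results.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation, kept below 2^31.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- (as.double(master) %% 2147483647) + 0
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 2147483563
  }
  as.integer(h %% 2147483562 + 1)
}

# Bilinear interpolation of matrix `m` sampled at (gx, gy) grid lines,
# evaluated at query points (xq, yq). Queries are clamped to the grid hull.
bilinear <- function(gx, gy, m, xq, yq) {
  xq <- pmin(pmax(xq, gx[1]), gx[length(gx)])
  yq <- pmin(pmax(yq, gy[1]), gy[length(gy)])
  ix <- pmin(pmax(findInterval(xq, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(yq, gy), 1L), length(gy) - 1L)
  wx <- (xq - gx[ix]) / (gx[ix + 1L] - gx[ix])
  wy <- (yq - gy[iy]) / (gy[iy + 1L] - gy[iy])
  # nested form: exact for constant fields (no weight round-off)
  v1 <- m[cbind(ix, iy)] + wx * (m[cbind(ix + 1L, iy)] - m[cbind(ix, iy)])
  v2 <- m[cbind(ix, iy + 1L)] +
    wx * (m[cbind(ix + 1L, iy + 1L)] - m[cbind(ix, iy + 1L)])
  v1 + wy * (v2 - v1)
}

# Wrap an angle in degrees to (-180, 180].
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Smooth random field on a lattice: sum of a few random cosine modes,
# normalized to [-1, 1]. Used by the synthetic-geometry generator.
smooth_random_field <- function(x, y, n_modes = 3L, max_cycles = 1.5) {
  lx <- diff(range(x)) + .Machine$double.eps
  ly <- diff(range(y)) + .Machine$double.eps
  f <- matrix(0, length(x), length(y))
  for (k in seq_len(n_modes)) {
    fx <- stats::runif(1, 0.2, max_cycles) / lx
    fy <- stats::runif(1, 0.2, max_cycles) / ly
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(1, 0.3, 1)
    f <- f + amp * outer(cos(2 * pi * fx * x + ph[1]),
                         cos(2 * pi * fy * y + ph[2]))
  }
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
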