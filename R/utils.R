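# Shared internal helpers.

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Normal draw truncated to [lo, hi] by resampling, with a final clamp so the
# bound is guaranteed even for extreme parameters.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf, tries = 50L) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(tries)) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

notice <- function(...) message("[dmerwkv] ", sprintf(...))

# Light Gaussian blur (separable), replicate borders; sigma 0 is identity.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0.01) return(x)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  xr <- x[pad_idx(nrow(x)), , drop = FALSE]
  x1 <- apply(xr, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  x1 <- x1[(r + 1):(r + nrow(x)), , drop = FALSE]
  xc <- x1[, pad_idx(ncol(x)), drop = FALSE]
  x2 <- t(apply(xc, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
  x2[, (r + 1):(r + ncol(x)), drop = FALSE]
}
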