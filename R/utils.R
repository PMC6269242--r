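`%||%` <- function(x, y) if (is.null(x)) y else x

## Derive a child RNG seed from a base seed and integer indices, staying
## within R's 32-bit integer range. Splitmix-style mixing keeps cell seeds
## decorrelated in study loops.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed)
  for (k in idx) {
    h <- (h * 69069 + as.double(k) * 40503 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

## Run an expression with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## standard normal density grid for numerical integration over latents
.norm_grid <- function(k = 201, lim = 8) {
  x <- seq(-lim, lim, length.out = k)
  w <- stats::dnorm(x)
  w <- w / sum(w)
  list(x = x, w = w)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
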