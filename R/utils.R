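# Internal helpers shared across the package.

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != trunc(seed)) {
    stop("`seed` must be a single integer.", call. = FALSE)
  }
  as.integer(seed)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive `n` reproducible child seeds (< 2^31) from one master seed.
spawn_seeds <- function(seed, n) {
  with_local_seed(check_seed(seed), sample.int(.Machine$integer.max, n))
}

# Swap quadrants so the zero-frequency sample sits at the array centre.
fftshift2 <- function(x) {
  nr <- nrow(x)
  nc <- ncol(x)
  x[c((floor(nr / 2) + 1L):nr, 1L:floor(nr / 2)),
    c((floor(nc / 2) + 1L):nc, 1L:floor(nc / 2))]
}

# Round half away from zero (for non-negative input: half-up).
round_half_up <- function(x) floor(x + 0.5)
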