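# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
# All stochastic functions in the package route their randomness through
# this so that no call mutates the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-local sub-seed from a manifest seed; keeps results
# reproducible when stages are re-run independently. Stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587) + 1L
}

# Summed-area table of a 2D matrix, zero-padded so that the sum over
# rows r0..r1, cols c0..c1 (1-based, inclusive) is
# S[r1+1,c1+1] - S[r0,c1+1] - S[r1+1,c0] + S[r0,c0].
summed_area_table <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Vectorised mean over `side x side` squares with 1-based top-left corners
# (rows, cols) on matrix `m` via its summed-area table.
square_means <- function(sat, rows, cols, side) {
  r1 <- rows + side
  c1 <- cols + side
  n <- nrow(sat)
  idx <- function(r, c) (c - 1L) * n + r
  tot <- sat[idx(r1, c1)] - sat[idx(rows, c1)] -
    sat[idx(r1, cols)] + sat[idx(rows, cols)]
  tot / (side * side)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}
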