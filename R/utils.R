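# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a global seed, so each generator draws
# from its own stream and fixtures stay reproducible piecewise. Kept below
# 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer((s * 10007 + abs(as.double(offset)) * 7919) %% 2147483647)
}

# Evaluate an expression with a local RNG state, leaving the caller's
# .Random.seed untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# n-1 standard deviation alongside mean, the "mean +/- sd" summary used for
# replicate endpoints throughout.
mean_sd <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
       n = length(x))
}
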