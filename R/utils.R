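# Internal helpers shared across modules.

# Evaluate code with a local, restored RNG state so simulation functions
# take an explicit seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range R requires.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k) %% 2147483647)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) stop(name, " must be > ", lower)
  if (!strict_lower && x < lower) stop(name, " must be >= ", lower)
  if (x > upper) stop(name, " must be <= ", upper)
  invisible(x)
}
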