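#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero,
#' the convention used throughout the package when formatting percentages
#' and 4-decimal diversity statistics (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(89.52)  # 90 at digits = 0
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m + sign(x) * 0.5) / m
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions never disturb user-level streams.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive `n` distinct child seeds (< 2^31) from a master
# seed; used so each pipeline stage / sampler run has its own stream.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
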