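#' Derive a stage-specific RNG seed from a master seed
#'
#' Deterministic linear-congruential mix so that every random stage of a run
#' gets its own reproducible stream. The result is always a valid 32-bit
#' integer seed.
#'
#' @param seed master seed (integer).
#' @param salt small integer distinguishing the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 69069 * 2^31 < 2^53, so the double-precision product is exact
  as.integer((abs(seed) * 69069 + 12345 + abs(salt) * 2027) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Zero-truncated normal draws by rejection; exact for sd = 0.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (any(sd < 0)) abort("standard deviations must be >= 0")
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1L) mean[bad] else mean,
                    if (length(sd) > 1L) sd[bad] else sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

# Fisher transform helpers (atanh/tanh with names kept for readability).
fisher_z <- function(r) atanh(r)
inv_fisher_z <- function(z) tanh(z)
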