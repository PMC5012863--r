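# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
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

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Fisher z with clamping for use inside simulation pipelines, where a pair of
# fully phase-locked regions can produce |r| = 1 to machine precision.
fisher_z_clamped <- function(r, eps = 1e-7) {
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
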