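#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# Stable 32-bit string digest -> bucket in [0, n_bits).
# murmur32 gives 8 hex chars; split to stay inside R's 32-bit integers.
hash_to_bucket <- function(strings, n_bits) {
  vapply(strings, function(s) {
    h <- digest::digest(s, algo = "murmur32", serialize = FALSE)
    hi <- strtoi(substr(h, 1L, 4L), 16L)
    lo <- strtoi(substr(h, 5L, 8L), 16L)
    as.integer((hi * 65536 + lo) %% n_bits)
  }, integer(1), USE.NAMES = FALSE)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a base seed and a label.
derive_seed <- function(seed, label) {
  h <- digest::digest(paste0(seed, "/", label), algo = "murmur32",
                      serialize = FALSE)
  (strtoi(substr(h, 1L, 4L), 16L) * 65536 + strtoi(substr(h, 5L, 8L), 16L)) %%
    2147483647
}

geometric_mean <- function(x) exp(mean(log(x)))

# sample() misbehaves on scalar x; draw uniformly from an integer range
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
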