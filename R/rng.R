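# Deterministic named substreams.  Every generator draws from its own stream
# derived from (seed, name), so adding a generator (or changing how many
# draws one makes) never perturbs the output of another.

substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65521
  # stays below 2^31 - 1 for any input seed
  as.integer((abs(seed) %% 32003 + 1) * 65521 + h)
}

# Evaluate `code` under a seed derived from (seed, name), restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  code
}
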