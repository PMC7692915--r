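# Internal helpers: seeded evaluation and seed substreams.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state so
# that seeded package functions never perturb the user's random stream.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a named substream seed from a master seed so that the survey, OTU
# and flume generators can be re-run independently with stable streams.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream = c("survey", "otu", "flume",
                                            "bootstrap", "permutation")) {
  stream <- match.arg(stream)
  offset <- c(survey = 1L, otu = 2L, flume = 3L,
              bootstrap = 4L, permutation = 5L)[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
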