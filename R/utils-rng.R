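# Seeded-evaluation and stream-derivation helpers. Every stochastic piece of
# the generator draws from its own derived stream so that subjects (and
# products within a subject) never share randomness, and so that any component
# can be regenerated in isolation.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG state
#' afterwards, so seeded helpers never disturb the session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a substream seed from a master seed
#'
#' Deterministically hashes `(master_seed, subject, product)` into a 31-bit
#' integer seed. Distinct (subject, product) pairs map to distinct streams
#' with overwhelming probability, keeping every subject's E-field, FC and
#' parameter draws independent and individually reproducible.
#'
#' @param master_seed Integer master seed of the cohort.
#' @param subject Subject index (or 0 for cohort-level streams).
#' @param product Character tag for the component ("params", "fc", ...).
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
stream_seed <- function(master_seed, subject, product) {
  h <- as.double(master_seed %% 2147483647L)
  for (byte in utf8ToInt(paste0(product, ":", subject))) {
    h <- (h * 131 + byte) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}
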