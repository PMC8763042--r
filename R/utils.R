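# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards: stochastic routines take explicit seeds
# and leave no hidden global state behind.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be supplied as a single integer", call. = FALSE)
  as.integer(seed)
}
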