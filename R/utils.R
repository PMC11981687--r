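# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded simulation calls do not perturb the session.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Midpoint-convention median of the valid entries (stats::median already uses
# the midpoint for even counts; this also drops NA and respects `valid`).
valid_median <- function(x, valid = NULL) {
  if (!is.null(valid)) x <- x[valid]
  stats::median(x, na.rm = TRUE)
}
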