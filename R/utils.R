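# Internal helpers shared across modules.

# Evaluate `expr` under a temporary, seeded RNG state, restoring the caller's
# state afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for (seed, i, j) replicate grids; stays in 32-bit range.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 1000003 +
                as.numeric(j) * 7177) %% 2147483587 + 1)
}

# floor(fraction * n) with a guard against binary-float artifacts
# (0.29 * 100 is 28.999... in double arithmetic).
floor_fraction <- function(fraction, n) {
  as.integer(floor(fraction * n + 1e-9))
}

# Writes a provenance JSON (parameters + seed) beside an output file.
write_provenance <- function(path, params) {
  jsonlite::write_json(params, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paste0(path, ".provenance.json"))
}
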