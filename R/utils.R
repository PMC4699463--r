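# Internal helpers: structured error conditions and seed scoping.

abort_fneo <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fneo_error", "error")))
}

validation_error <- function(msg) abort_fneo(msg, "fneo_validation_error")
domain_error     <- function(msg) abort_fneo(msg, "fneo_domain_error")
fit_error        <- function(msg) abort_fneo(msg, "fneo_fit_error")
identifiability_error <- function(msg) abort_fneo(msg, "fneo_identifiability_error")
parse_error      <- function(msg) abort_fneo(msg, "fneo_parse_error")
schema_error     <- function(msg) abort_fneo(msg, "fneo_schema_error")
numeric_error    <- function(msg) abort_fneo(msg, "fneo_numeric_error")

check_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validation_error(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}

check_numeric_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
    validation_error(sprintf("'%s' must be finite numeric", name))
  invisible(x)
}

# Evaluate `code` under `seed` without clobbering the caller's RNG stream.
# seed = NULL leaves the ambient stream untouched (and consumes from it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    validation_error("'seed' must be a single integer or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive n child seeds (< 2^31) from a master seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
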