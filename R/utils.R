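# Internal helpers: classed errors, scoped RNG, small numeric utilities.

rehh_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "rehhscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

nchoose2 <- function(n) n * (n - 1) / 2

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_fraction <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    rehh_abort(sprintf("`%s` must be a single value in [0, 1]", name),
               "rehhscan_config_error")
  invisible(x)
}
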