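# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic small integer derived from a participant label, used to give
# each participant an independent but reproducible RNG stream.
participant_key <- function(participant_id) {
  sum(utf8ToInt(as.character(participant_id)) * seq_along(utf8ToInt(as.character(participant_id)))) %% 100000L
}

derive_seed <- function(seed, salt, key = 0L) {
  as.integer((as.numeric(seed) * 48271 + salt * 7919 + key * 104729) %% 2147483629)
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "natfnirs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
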