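# Internal helpers: seeding and RNG hygiene.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic 31-bit child seed from a master seed plus arbitrary labels.
# Polynomial string hash mod the Mersenne prime 2^31 - 1, so adding a task
# or subject never perturbs the streams of the others.
child_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- 0
  m <- 2147483647
  for (cp in utf8ToInt(key)) {
    h <- (h * 131 + cp) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}
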