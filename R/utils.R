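# Internal helpers shared across modules.

# One user-facing seed feeds a named sub-stream per generated artifact, so
# adding an artifact never perturbs the draws of the others. The stream seed
# is a deterministic 31-bit hash of (seed, stream name).
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, stream);
# the caller's RNG state is restored afterwards. seed = NULL leaves the
# global stream untouched (non-reproducible draws).
with_stream <- function(seed, stream, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(stream_seed(seed, stream))
  force(expr)
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be greater than %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be at least %s.", name, format(min)))
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
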