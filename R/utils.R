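# Internal helpers: argument checks, seed plumbing, tiny hashing.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain("`%s` = %g is outside its valid range", name, x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_domain("`%s` must be a single integer", name)
  if (x < lower) stop_domain("`%s` must be >= %d", name, lower)
  invisible(as.integer(x))
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-participant seed streams derived from one master seed by
# iterating a MINSTD (Lehmer) generator. Stream i depends only on (master, i),
# never on cohort size, so adding participants leaves earlier ones untouched.
# All arithmetic stays below 2^53 so doubles are exact.
participant_seeds <- function(master, n) {
  s <- (abs(as.double(master)) %% 2147483645) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- as.integer(s)
  }
  out
}

# Offset a participant seed into a per-stage substream (cortisol, calibration,
# main task, heart rate, questionnaires) so stages never share draws.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 1299721 * stage) %% 2147483647)
}

# Small polynomial fingerprint of a string (config provenance in manifests);
# not cryptographic, just stable across platforms.
text_fingerprint <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
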