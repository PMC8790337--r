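# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so generators do not perturb the caller's stream.
#' A `NULL` seed evaluates the code against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream derivation: one user-facing seed fans out to
# independent per-stage seeds. Kept below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  ((as.numeric(seed) %% 1e6) * 1000003 + as.numeric(offset) * 7919 + 1) %% 2147483647
}

# sprintf-style stop()/warning() without call noise
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Format a value at n significant figures for display (reports round at
# 2 s.f.; full precision is always kept in the underlying objects).
fmt_signif <- function(x, digits = 2) {
  ifelse(is.finite(x),
         trimws(formatC(signif(x, digits), format = "g", digits = digits)),
         as.character(x))
}

# FNV-1a hash of a character scalar, reported as hex. Used to stamp
# pipeline outputs with a configuration fingerprint; not cryptographic.
fnv1a_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
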