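# Internal helpers shared across modules.

.cordti_cache <- new.env(parent = emptyenv())

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Polynomial string hash kept below 2^31 so it can seed R's RNG; exact in
# double arithmetic because intermediate products stay below 2^53.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

# Deterministic sub-seed derived from a base seed plus string labels.
derive_seed <- function(seed, ...) {
  lab <- paste(c(format(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  as.integer(fnv1a32(lab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Sample SD with the n-1 denominator (the package-wide convention).
sample_sd <- function(x) stats::sd(x)
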