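`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse runs of whitespace and trim
#' @param x character vector
#' @return character vector with leading/trailing whitespace removed and
#'   internal whitespace runs collapsed to single spaces
#' @keywords internal
trim_collapse <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

sorted_unique <- function(x) sort(unique(as.character(x)))

stop_gc <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' FNV-1a 32-bit digest of a string (hex)
#'
#' Small stable digest used to fingerprint prompt payloads in the exchange
#' log without storing the full payload twice.
#' @param text a single string
#' @return 8-character lowercase hex digest
#' @keywords internal
fnv1a32 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(paste(text, collapse = "\n")))
  # 32-bit arithmetic in double precision; 2^32 fits exactly
  h <- 2166136261
  prime <- 16777619
  m32 <- 2^32
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * prime) %% m32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

# xor of two non-negative doubles < 2^32 without integer overflow
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 2^16), as.integer(b %% 2^16))
  hi <- bitwXor(as.integer(a %/% 2^16), as.integer(b %/% 2^16))
  hi * 2^16 + lo
}

# Run `expr` under a private RNG stream stored in environment `env` (field
# `rng_state`), leaving the caller's .Random.seed untouched. Used by the mock
# backend so its draws are a pure function of the backend seed and call
# order, independent of user code.
with_private_rng <- function(env, seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  if (is.null(env$rng_state)) {
    set.seed(seed)
  } else {
    assign(".Random.seed", env$rng_state, envir = globalenv())
  }
  out <- force(expr)
  env$rng_state <- get(".Random.seed", envir = globalenv())
  out
}
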