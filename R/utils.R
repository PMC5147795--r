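#' @keywords internal
"_PACKAGE"

## Seed discipline: every stochastic entry point takes an explicit `seed`.
## `with_seed()` scopes the RNG so package functions never clobber the
## caller's random stream; `child_seed()` derives per-subject / per-stage
## seeds deterministically from a parent seed (kept below 2^31 - 1).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting of one integer seed into per-subject or
#' per-stage seeds, so that any element of a seeded run can be regenerated
#' in isolation. The derivation is a fixed affine map modulo 2^31 - 1.
#'
#' @param seed parent seed (integer).
#' @param index non-negative integer index of the child stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) >= 1L, all(index >= 0))
  m <- 2147483647  # 2^31 - 1 (prime)
  s <- (as.numeric(seed) %% m + 104729 * (as.numeric(index) + 1)) %% m
  as.integer(ifelse(s == 0, 1, s))
}

## 32-bit FNV-1a hash of a string; used to stamp output artifacts with a
## short configuration fingerprint. Arithmetic kept in doubles (exact below
## 2^53) with explicit 2^32 reduction.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- mul32(xor32(h, b), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## (a * b) mod 2^32 without exceeding double precision
mul32 <- function(a, b) {
  hi <- floor(a / 65536)
  lo <- a - hi * 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

xor32 <- function(a, b) {
  ## bitwXor works on 32-bit signed ints; map a (in [0, 2^32)) into that range
  ai <- as.integer(a - (a >= 2147483648) * 4294967296)
  r <- bitwXor(ai, as.integer(b))
  r + (r < 0) * 4294967296
}

stop_domain <- function(...) {
  stop(structure(class = c("gazescreen_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
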