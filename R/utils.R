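# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so seeded generators never perturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# djb2 string hash modulo 2^31-1, reported as 8 hex digits; used only to tag
# outputs with a config fingerprint (not cryptographic).
djb2_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (c in utf8ToInt(x)) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_sgm <- function(...) stop(sprintf(...), call. = FALSE)

assert_finite_matrix <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_sgm("%s must be a numeric matrix", name)
  }
  if (any(!is.finite(m))) stop_sgm("%s contains NaN/Inf entries", name)
}

# Hz -> angular frequency (rad/s); the single conversion point for grids.
hz_to_omega <- function(f) 2 * pi * f
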