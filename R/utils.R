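# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit seed derived from a master seed; stays < 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) + 104729 * as.double(index)) %% 2147483629)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("`%s` must be finite numeric (got non-finite or non-numeric values)", name))
  }
  invisible(x)
}

# Linear-in-age generative parameter: scalar (constant) or c(intercept, slope).
lin_at <- function(par, age) {
  if (length(par) == 1L) return(rep(par, length(age)))
  par[1L] + par[2L] * age
}

# Tiny FNV-1a hash of a string, for provenance records (no external digest dep).
fnv1a <- function(text) {
  bytes <- utf8ToInt(text)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
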