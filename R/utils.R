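# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Practical range of AlphaFold PAE output, in Angstrom.
.PAE_MIN <- 0.2
.PAE_MAX <- 31.75

# Derive a deterministic per-stream seed from a master seed and a stream
# index, staying inside 32-bit integer range. Arithmetic is done in doubles
# (exact below 2^53) before the modulus.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 1000003 + stream * 7919 + 1) %% 2147483647)
}

# Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_slimpae <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "slimpae_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_slimpae("'%s' must be a single finite number", "slimpae_domain_error", name)
  }
  if (x < lo || x > hi) {
    stop_slimpae("'%s' = %g is outside [%g, %g]", "slimpae_domain_error",
                 name, x, lo, hi)
  }
  invisible(x)
}
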