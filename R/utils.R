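#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stream * 16807) %% 2147483629 + 1)
}

# Run `expr` under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x)) stop_arg("`%s` must be numeric", name)
  if (length(x) < min_len) {
    stop_arg("`%s` must have length >= %d (got %d)", name, min_len, length(x))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_arg("`%s` contains non-finite values", name)
  }
  invisible(x)
}
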