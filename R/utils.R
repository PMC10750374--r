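#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# go through this so that library calls never clobber the user's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a reproducible child seed from a base seed and one or more keys.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    for (ch in utf8ToInt(as.character(k))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("mstateri_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero-mean a vector / the columns of a matrix (channels along rows)
center_cols <- function(m) sweep(m, 2L, colMeans(m), "-")
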