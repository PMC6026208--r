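# Internal helpers: seeded RNG streams and small validators.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed and a stream tag, so
# that adding a generator never perturbs the draws of another.  Plain
# polynomial string hash folded into the positive 31-bit integer range.
#' @keywords internal
#' @noRd
child_seed <- function(master_seed, tag) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  expr
}

#' @keywords internal
#' @noRd
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' @keywords internal
#' @noRd
assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
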