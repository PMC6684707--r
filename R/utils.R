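# Internal helpers shared across modules.

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed; keeps results < 2^31 - 1 so they
# are always representable as R integers.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

stop_bad_arg <- function(name, why) {
  stop(sprintf("invalid `%s`: %s", name, why), call. = FALSE)
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(name, "must be a single finite number")
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok)
    stop_bad_arg(name, sprintf("must lie in %s", if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_bad_arg(name, "must be a single finite positive number")
  invisible(x)
}

check_cols <- function(df, cols, name) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_bad_arg(name, sprintf("missing column(s): %s",
                               paste(miss, collapse = ", ")))
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap data.frame construction for hot per-trial paths (no name
# deparsing, no checks; all columns must share one length).
quick_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1L]])))
}
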