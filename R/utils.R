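# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic per-unit sub-seed so that adding trials/animals never
# perturbs the streams of earlier ones. Kept within 32-bit integer range.
substream_seed <- function(seed, index, salt = 0) {
  as.integer((abs(seed) * 69069 + index * 104729 + salt * 7919) %% 2147483629)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s] (got %s).", name,
                  format(min), format(max), format(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  assert_scalar_number(x, name, min = min)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Running median with a shrinking window at the edges; length-preserving.
running_median <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    median(x[lo:hi])
  }, numeric(1))
}
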