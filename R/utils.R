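# internal helpers

# run `expr` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL leaves the RNG alone
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# deterministic sub-seed for a named stage, derived from one root seed;
# kept below 2^31 so it is always a valid R integer seed
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "qgsel_input_error")
  }
  invisible(x)
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(0.5 * (m + t(m)), symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

# nearest symmetric matrix
symm <- function(m) 0.5 * (m + t(m))

# column of a data frame, or a default when absent (tibbles warn on `$` misses)
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
}
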