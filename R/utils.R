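# Small argument-checking helpers used throughout the package.  All raise
# classed conditions so callers (and tests) can distinguish configuration
# errors from data errors.

stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "rfidforage_config_error")
}

stop_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "rfidforage_data_error")
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < 0 || x > 1) {
    stop_config("`%s` must be a single probability in [0, 1], got %s",
                name, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < 0) {
    stop_config("`%s` must be a single finite non-negative number", name)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_config("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

assert_reward <- function(x, name = "reward") {
  bad <- setdiff(unique(x), REWARD_LEVELS)
  if (length(bad) > 0) {
    stop_data("`%s` contains values other than 'nectar'/'pollen': %s",
              name, paste(bad, collapse = ", "))
  }
  invisible(x)
}
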