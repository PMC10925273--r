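# internal numeric helpers shared by the estimators

# log(mean(exp(x))) without intermediate overflow; safe for |x| up to ~700+
# because the max is factored out first.
log_mean_exp <- function(x) {
  n <- length(x)
  if (n == 0L) stop("log_mean_exp: empty input")
  m <- max(x)
  if (!is.finite(m)) {
    # all -Inf -> mean is 0 -> log is -Inf; +Inf dominates
    return(m)
  }
  m + log(sum(exp(x - m))) - log(n)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive, got %g", name, x), call. = FALSE)
  }
  invisible(as.numeric(x))
}

assert_samples <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop(sprintf("'%s' must contain at least one sample", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains non-finite samples", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# deterministic 32-bit-safe child seed for window `index` (1-based) of
# direction `dir_index` (1 forward, 2 backward) under root seed `seed`
child_seed <- function(seed, index, dir_index = 1L) {
  m <- 2147483647 # 2^31 - 1
  as.integer((as.double(seed) * 1009 + 101 * dir_index + index) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
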