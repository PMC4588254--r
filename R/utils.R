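# Internal condition helpers. All user-facing failures signal classed
# conditions so callers (and the CLI) can distinguish validation errors
# (exit 2) from degenerate-statistics signals (exit 3).

stop_pelvimetrix <- function(msg, class = "pelvimetrix_validation", ...) {
  stop(errorCondition(msg, class = c(class, "pelvimetrix_error"), ...))
}

warn_degenerate <- function(msg, ...) {
  warning(warningCondition(msg,
    class = c("pelvimetrix_degenerate", "pelvimetrix_warning"), ...
  ))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_pelvimetrix(sprintf("%s must be finite numeric, got: %s",
      what, paste(utils::head(format(x), 6), collapse = ", ")))
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Seeds are kept below 2^31-1 so they are valid R integers.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed %% 2147483647L))
  }
  expr
}

# Derive a child seed from a parent seed and stream indices; stays < 2^31-1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  primes <- c(104729, 7919, 15485863, 32452843, 49979687)
  s <- as.numeric(seed)
  for (i in seq_along(idx)) {
    s <- (s + primes[((i - 1L) %% length(primes)) + 1L] * (idx[i] + 1)) %% 2147483647
  }
  as.integer(s) + 1L
}

fmt_num <- function(x, digits = 3) {
  out <- formatC(x, format = "f", digits = digits)
  out[is.na(x)] <- "NA"
  out
}
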