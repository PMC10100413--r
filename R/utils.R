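# Shared internal helpers: seed streams, month arithmetic, argument checks.

#' Derive a child seed from a global seed and a stream label
#'
#' Every stochastic generator in the package draws its randomness from a
#' stream-specific child seed so that adding or reordering generator calls
#' does not perturb other streams.  The child seed is a deterministic hash of
#' the global integer seed and a character stream label, reduced modulo
#' 2^31 - 1 so it is always a valid R integer.
#'
#' @param seed Global integer seed.
#' @param stream Character scalar naming the stream (e.g. `"community"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "community")
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# consecutive first-of-month Date sequence
month_seq <- function(from, n_months) {
  seq(lubridate::floor_date(as.Date(from), "month"), by = "month",
      length.out = n_months)
}

# month-of-year integer 1..12
month_of_year <- function(month) as.integer(format(as.Date(month), "%m"))

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(as.integer(x))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%s, %s%s.", name,
                  if (open_lower) "(" else "[", format(lower), format(upper),
                  if (open_upper) ")" else "]"))
  }
  invisible(as.numeric(x))
}

# Offset rule for log transforms of quantities that may contain zeros:
# if any value is zero, add half the smallest positive observed value;
# otherwise leave untouched so positive data are logged exactly.
log_with_offset <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  eps <- if (any(x == 0, na.rm = TRUE)) {
    if (length(pos) == 0) {
      abort("cannot log-transform: all values are zero")
    }
    min(pos) / 2
  } else {
    0
  }
  log(x + eps)
}
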