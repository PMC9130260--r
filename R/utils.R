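# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index,
# so independent stages (or per-depth decoder streams) get decorrelated,
# order-independent RNG without sharing one global stream.
derive_seed <- function(master, stream) {
  master <- as.double(master)
  stream <- as.double(stream)
  # Weyl-style mixing; kept in double precision, reduced below 2^31.
  x <- (master * 48271 + stream * 2246822519 + 374761393) %% 2147483629
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (length(x) != 1 || (!allow_na && (is.na(x) || !is.finite(x)))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  if (length(x) != 1 || is.na(x) || x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

#' Convert AM depth in dB re: 100% to a linear modulation index
#'
#' Depths are expressed on a decibel scale relative to full (100%) modulation:
#' 0 dB corresponds to modulation index m = 1 and more negative values to
#' shallower modulation, with m = 10^(depth_db / 20).
#'
#' @param depth_db Numeric vector of AM depths in dB re: 100%; must be <= 0.
#' @return Numeric vector of modulation indices in (0, 1].
#' @examples
#' db_to_linear(c(0, -6, -20))
#' @export
db_to_linear <- function(depth_db) {
  if (!is.numeric(depth_db) || anyNA(depth_db)) {
    abort("`depth_db` must be numeric and non-missing.")
  }
  if (any(depth_db > 0)) {
    abort("`depth_db` must be <= 0 (0 dB corresponds to 100% modulation).")
  }
  10^(depth_db / 20)
}

#' Convert a linear modulation index to AM depth in dB re: 100%
#'
#' @param m Modulation index in (0, 1].
#' @return Depth in dB re: 100% (<= 0).
#' @export
linear_to_db <- function(m) {
  if (any(m <= 0 | m > 1)) abort("`m` must be in (0, 1].")
  20 * log10(m)
}
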