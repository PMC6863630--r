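#' Convert a duration in milliseconds to a whole number of samples
#'
#' All window-to-sample conversions in the package go through this one
#' function so that rounding is consistent everywhere: durations are
#' rounded to the nearest integer number of sample periods.
#'
#' @param ms Duration in milliseconds (vectorised).
#' @param sampling_rate Sampling rate in Hz.
#' @return Integer vector of sample counts.
#' @export
#' @examples
#' ms_to_samples(0.2, 20000) # 4 samples at 20 kHz
ms_to_samples <- function(ms, sampling_rate) {
  stopifnot(is.numeric(ms), is.numeric(sampling_rate), sampling_rate > 0)
  as.integer(round(ms / 1000 * sampling_rate))
}

#' Convert seconds to a 1-based sample index offset
#' @noRd
s_to_samples <- function(s, sampling_rate) {
  as.integer(round(s * sampling_rate))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. A NULL seed uses (and
# advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a distinct child seed from a base seed, staying inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) {
    return(NULL)
  }
  # double arithmetic keeps intermediates exact (< 2^53) and the
  # result inside the 32-bit integer range
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147480963)
}

# round-half-up, used when reporting integer percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

stop_arg <- function(...) abort(paste0(...), class = "optopallidum_argument_error")
stop_validation <- function(...) abort(paste0(...), class = "optopallidum_validation_error")
stop_format <- function(...) abort(paste0(...), class = "optopallidum_format_error")
stop_protocol <- function(...) abort(paste0(...), class = "optopallidum_protocol_error")
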