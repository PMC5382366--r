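#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr map2 pmap imap
NULL

# Weighted sums are rounded to this many decimals before the sign test so
# integer-weight networks behave like exact integer arithmetic.
WS_DIGITS <- 12L

#' Derive a stage seed from a master seed
#'
#' All stochastic stages derive their own seed from one master seed plus a
#' stage counter, so adding a stage never perturbs the random streams of
#' earlier stages.
#'
#' @param seed Master integer seed.
#' @param stage Non-negative integer stage counter.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729 + 1) %%
    2147483647)
}

assert_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", what, "` must be TRUE or FALSE"))
  }
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(paste0("`", what, "` must be a single integer >= ", min))
  }
}

assert_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", what, "` must be a single number"))
  }
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", what, "` must be a single string"))
  }
}
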