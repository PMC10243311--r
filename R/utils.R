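# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Table rendering in this package rounds half away from zero (so 2.85 -> 2.9,
#' -2.85 -> -2.9), matching how the clinical tables are printed, whereas base
#' [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(1.05, 2.85, -2.85), 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge guards against 2.85 * 10 == 28.499999... representation error
  z <- abs(x) * p
  sign(x) * floor(z + 0.5 + 1e-9) / p
}

# classed condition helpers -------------------------------------------------

qa_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "breathqa_error")))
}

abort_format <- function(msg, ...) qa_abort(msg, "breathqa_format_error", ...)
abort_data <- function(msg, ...) qa_abort(msg, "breathqa_data_error", ...)
abort_io <- function(msg, ...) qa_abort(msg, "breathqa_io_error", ...)
abort_config <- function(msg, ...) qa_abort(msg, "breathqa_config_error", ...)
# unanalyzable input: too few breaths/marks/records to compute a statistic
abort_insufficient <- function(msg, ...) qa_abort(msg, "breathqa_insufficient_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive an independent RNG seed for a named stream from one master seed, so
# that adding draws to one component does not perturb another. Kept below
# 2^31 - 1 (R integers are 32-bit).
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

# Evaluate expr under the named stream's seed without disturbing the caller's
# RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) abort_config(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) abort_config(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
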