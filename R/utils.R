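`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

# Deterministic sub-stream seed for per-channel / per-subject generation.
# Keeps derived seeds inside 32-bit integer range.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647L)
}
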