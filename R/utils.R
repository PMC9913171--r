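#' Round a percentage the way clinical tables print it
#'
#' Rounds to the nearest integer with halves going away from zero
#' (so 86.5 -> 87), matching the convention used in diagnostic-performance
#' tables.  Base `round()` rounds half to even and would print 86 instead.
#'
#' @param x numeric vector of percentages (or any numeric).
#' @return integer-valued numeric vector; `NA` stays `NA`.
#' @export
#' @examples
#' round_pct(100 * 40 / 46)  # 87
#' round_pct(100 * 33 / 39)  # 85
round_pct <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# internal: stop with a classed error so tests can assert on the condition
abort_blastscore <- function(msg, class) {
  rlang::abort(msg, class = c(class, "blastscore_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
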