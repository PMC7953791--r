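# Classed condition helpers so callers can branch on error kinds
# (testthat's expect_error(class = ...) relies on these).

abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ihcdiff_error")))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name),
          "ihcdiff_argument_error")
  }
}
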