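#' @importFrom methods new validObject is slot
#' @importFrom stats optim runif rnorm median approx sd setNames
#' @importFrom utils read.table write.table head combn
NULL

.assertScalarNumeric <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

# stable lexicographic order of item keys, used for all score tie-breaks
.tieOrder <- function(score, key, decreasing = FALSE) {
  order(if (decreasing) -score else score, key, method = "radix")
}

.msg <- function(...) {
  if (isTRUE(getOption("coreosc.verbose", FALSE))) message(...)
}
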