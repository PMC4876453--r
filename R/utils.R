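## internal numeric helpers

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## row-wise log-sum-exp for a matrix
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  invisible(x)
}
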