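# internal numeric helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pmrkin <- function(...) stop(sprintf(...), call. = FALSE)

# canonical unordered pair key, lexicographic
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}
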