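# internal numerical helpers

# log(1 - exp(-a)) for a > 0, stable for both small and large a
log1mexp <- function(a) {
  out <- numeric(length(a))
  big <- a > log(2)
  out[big] <- log1p(-exp(-a[big]))
  out[!big] <- log(-expm1(-a[!big]))
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_if_not_positive <- function(..., .what = NULL) {
  vals <- list(...)
  nms <- if (is.null(.what)) names(vals) else .what
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be a finite positive number", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
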