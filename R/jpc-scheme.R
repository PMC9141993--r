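#' Joint progressive type-II censoring schemes
#'
#' Builds (and validates) the censoring scheme of a joint progressive
#' type-II censoring (JPC) life test pooling two lines of sizes `m` and `n`:
#' at the i-th observed failure, `R[i]` of the surviving pooled units are
#' withdrawn at random, and the test stops at the `k`-th failure.  A valid
#' scheme accounts for every unit: \eqn{\sum_{i=1}^k (R_i + 1) = m + n}.
#'
#' `R` may be given either as a length-`k` integer vector or in the compact
#' notation used in the reliability literature, e.g. `"(0(6),10(4),0(10))"`
#' meaning six zeros, four tens, ten zeros: `value(count)` expands to `count`
#' repetitions of `value`, and a bare `value` stands for itself.
#'
#' @param m,n sample sizes of line 1 and line 2.
#' @param k number of failures observed before termination.
#' @param R withdrawal plan: length-`k` vector of non-negative integers, or a
#'   notation string as above.
#'
#' @return An object of class `"jpc_scheme"`: a list with elements `m`, `n`,
#'   `k` and integer vector `R`.
#' @examples
#' jpc_scheme(m = 20, n = 25, k = 20, R = "(0(4),25,0(15))")
#' jpc_scheme(m = 2, n = 2, k = 2, R = c(1, 1))
#' @export
jpc_scheme <- function(m, n, k, R) {
  for (v in list(m = m, n = n, k = k)) {
    if (length(v) != 1 || !is.numeric(v) || v != round(v) || v < 1) {
      stop("'m', 'n' and 'k' must be positive integers", call. = FALSE)
    }
  }
  m <- as.integer(m); n <- as.integer(n); k <- as.integer(k)
  if (is.character(R)) R <- parse_scheme_notation(R)
  if (!is.numeric(R) || any(R != round(R)) || any(R < 0)) {
    stop("'R' must be a vector of non-negative integers", call. = FALSE)
  }
  R <- as.integer(R)
  if (length(R) != k) {
    stop(sprintf("scheme has %d withdrawal entries but k = %d", length(R), k),
         call. = FALSE)
  }
  if (k > m + n) stop("'k' cannot exceed m + n", call. = FALSE)
  if (sum(R + 1L) != m + n) {
    stop(sprintf(
      "scheme does not exhaust the units: sum(R + 1) = %d but m + n = %d",
      sum(R + 1L), m + n), call. = FALSE)
  }
  structure(list(m = m, n = n, k = k, R = R), class = "jpc_scheme")
}

# expand "(0(4),25,0(15))" -> c(rep(0,4), 25, rep(0,15))
parse_scheme_notation <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  s <- sub("^\\(", "", sub("\\)$", "", s))
  # split on commas not inside value(count) parentheses
  toks <- regmatches(s, gregexpr("[0-9]+(\\([0-9]+\\))?", s))[[1]]
  rebuilt <- paste(toks, collapse = ",")
  if (!nzchar(s) || rebuilt != s) {
    stop(sprintf("malformed scheme notation: '%s'", text), call. = FALSE)
  }
  unlist(lapply(toks, function(tk) {
    mt <- regmatches(tk, regexec("^([0-9]+)(?:\\(([0-9]+)\\))?$", tk))[[1]]
    val <- as.integer(mt[2])
    if (nzchar(mt[3])) rep(val, as.integer(mt[3])) else val
  }))
}

#' @export
format.jpc_scheme <- function(x, ...) {
  r <- rle(x$R)
  paste0("(", paste(ifelse(r$lengths > 1,
                           sprintf("%d(%d)", r$values, r$lengths),
                           sprintf("%d", r$values)), collapse = ","), ")")
}

#' @export
print.jpc_scheme <- function(x, ...) {
  cat(sprintf("Joint progressive type-II censoring scheme\n  m = %d, n = %d, k = %d\n  R = %s\n",
              x$m, x$n, x$k, format(x)))
  invisible(x)
}
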