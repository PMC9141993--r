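#' Joint progressively type-II censored samples
#'
#' Container for the observed data of a JPC life test: at each of the `k`
#' observed failures, the failure time `w[i]`, the line indicator `z[i]`
#' (1 if the failing unit came from line 1), and the split of the `R[i]`
#' withdrawn survivors into `s[i]` units from line 1 and `t[i]` from line 2.
#'
#' The constructor enforces the bookkeeping invariants of the design:
#' `w` strictly increasing, `s + t == R` componentwise, and conservation per
#' line, `k1 + sum(s) == m` and `k2 + sum(t) == n` where `k1 = sum(z)` and
#' `k2 = k - k1`.
#'
#' @param w strictly increasing vector of failure times (length `k`).
#' @param z 0/1 vector: 1 when the i-th failure is from line 1.
#' @param s,t non-negative integer vectors: withdrawals from line 1 / line 2
#'   at each failure.
#' @param scheme a [jpc_scheme].
#'
#' @return An object of class `"jpc_sample"`: list with `w`, `z`, `s`, `t`,
#'   `scheme`, and the derived failure counts `k1`, `k2`.
#' @seealso [rjpc()], [jpc_censor()], [jgied_fit()]
#' @examples
#' sch <- jpc_scheme(2, 2, 2, c(1, 1))
#' jpc_sample(w = c(1, 2), z = c(1, 0), s = c(1, 0), t = c(0, 1), scheme = sch)
#' @export
jpc_sample <- function(w, z, s, t, scheme) {
  if (!inherits(scheme, "jpc_scheme")) stop("'scheme' must be a jpc_scheme")
  k <- scheme$k
  if (length(w) != k || length(z) != k || length(s) != k || length(t) != k) {
    stop(sprintf("w, z, s, t must all have length k = %d", k), call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w <= 0)) stop("failure times must be positive")
  if (any(diff(w) <= 0)) stop("failure times 'w' must be strictly increasing")
  if (!all(z %in% c(0, 1))) stop("'z' must be a 0/1 line indicator")
  z <- as.integer(z); s <- as.integer(s); t <- as.integer(t)
  if (any(s < 0) || any(t < 0)) stop("withdrawal counts must be non-negative")
  if (!all(s + t == scheme$R)) {
    stop("withdrawal split violated: s[i] + t[i] must equal R[i]", call. = FALSE)
  }
  k1 <- sum(z); k2 <- k - k1
  if (k1 + sum(s) != scheme$m) {
    stop(sprintf("line-1 units not conserved: k1 + sum(s) = %d, m = %d",
                 k1 + sum(s), scheme$m), call. = FALSE)
  }
  if (k2 + sum(t) != scheme$n) {
    stop(sprintf("line-2 units not conserved: k2 + sum(t) = %d, n = %d",
                 k2 + sum(t), scheme$n), call. = FALSE)
  }
  structure(list(w = as.numeric(w), z = z, s = s, t = t,
                 scheme = scheme, k1 = k1, k2 = k2),
            class = "jpc_sample")
}

#' @export
as.data.frame.jpc_sample <- function(x, ...) {
  data.frame(index = seq_len(x$scheme$k), w = x$w, z = x$z, s = x$s, t = x$t)
}

#' @export
print.jpc_sample <- function(x, ...) {
  cat(sprintf("JPC sample: k = %d failures (k1 = %d from line 1, k2 = %d from line 2)\n",
              x$scheme$k, x$k1, x$k2))
  cat(sprintf("  m = %d, n = %d, scheme R = %s\n",
              x$scheme$m, x$scheme$n, format(x$scheme)))
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (x$scheme$k > 10) cat(sprintf("  ... %d more rows\n", x$scheme$k - 10))
  invisible(x)
}

#' Read and write JPC samples
#'
#' A `jpc_sample` is serialized as a CSV of the per-failure records
#' (`index, w, z, s, t`) together with a JSON sidecar holding the scheme
#' (`m`, `n`, `k`, `R`, and the compact notation).
#'
#' @param x a [jpc_sample].
#' @param file path of the CSV file.
#' @param scheme_file path of the JSON sidecar; defaults to `file` with its
#'   extension replaced by `.json`.
#' @return `write_jpc` returns `file` invisibly; `read_jpc` a [jpc_sample].
#' @export
write_jpc <- function(x, file, scheme_file = NULL) {
  if (is.null(scheme_file)) scheme_file <- sub("\\.[^.]*$", ".json", file)
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  sch <- x$scheme
  jsonlite::write_json(
    list(m = sch$m, n = sch$n, k = sch$k, R = sch$R, notation = format(sch)),
    scheme_file, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_jpc
#' @export
read_jpc <- function(file, scheme_file = NULL) {
  if (is.null(scheme_file)) scheme_file <- sub("\\.[^.]*$", ".json", file)
  d <- utils::read.csv(file)
  js <- jsonlite::read_json(scheme_file, simplifyVector = TRUE)
  sch <- jpc_scheme(js$m, js$n, js$k, js$R)
  jpc_sample(d$w, d$z, d$s, d$t, sch)
}
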