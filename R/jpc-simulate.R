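#' Simulate joint progressively type-II censored samples
#'
#' `rjpc` draws `m` lifetimes from GIED(`theta1`, `lambda`) and `n` from
#' GIED(`theta2`, `lambda`) and runs the JPC experiment: at each round the
#' smallest lifetime among the active units is the next observed failure,
#' after which `R[i]` of the surviving active units are withdrawn as a
#' uniformly random subset of the pooled risk set (so the line split of the
#' withdrawal is hypergeometric).  `jpc_censor` applies the same withdrawal
#' process to fixed lifetime vectors, which is how a complete real data set
#' is turned into a censored one for a given scheme.
#'
#' Ties between lifetimes have probability zero for continuous data but can
#' occur in rounded real data; they are broken in favour of line 1, then by
#' input order (a stable rule, so a fixed RNG state reproduces the sample).
#'
#' @param scheme a [jpc_scheme].
#' @param theta1,theta2,lambda GIED parameters of the two lines (shared
#'   `lambda`).
#' @param x1,x2 complete lifetime vectors for line 1 (length `m`) and line 2
#'   (length `n`).
#' @return A [jpc_sample].
#' @examples
#' sch <- jpc_scheme(20, 25, 20, "(0(4),25,0(15))")
#' set.seed(7)
#' rjpc(sch, theta1 = 1, theta2 = 1, lambda = 0.5)
#' @export
rjpc <- function(scheme, theta1, theta2, lambda) {
  stop_if_not_positive(theta1 = theta1, theta2 = theta2, lambda = lambda)
  if (!inherits(scheme, "jpc_scheme")) stop("'scheme' must be a jpc_scheme")
  jpc_censor(rgied(scheme$m, theta1, lambda),
             rgied(scheme$n, theta2, lambda), scheme)
}

#' @rdname rjpc
#' @export
jpc_censor <- function(x1, x2, scheme) {
  if (!inherits(scheme, "jpc_scheme")) stop("'scheme' must be a jpc_scheme")
  if (length(x1) != scheme$m || length(x2) != scheme$n) {
    stop("length(x1) must be m and length(x2) must be n", call. = FALSE)
  }
  if (any(c(x1, x2) <= 0)) stop("lifetimes must be positive")
  k <- scheme$k
  if (all(scheme$R == 0L)) {
    # no withdrawals: the sample is the pooled order statistics with labels
    life <- c(x1, x2)
    line1 <- c(rep(1L, scheme$m), rep(0L, scheme$n))
    ord <- order(life, -line1)  # ties: line 1 first
    w <- life[ord]
    if (any(diff(w) <= 0)) {
      w <- cummax(w) + cumsum(duplicated(cummax(w))) * .Machine$double.eps * max(w)
    }
    return(jpc_sample(w, line1[ord], rep(0L, k), rep(0L, k), scheme))
  }
  life <- c(x1, x2)
  line1 <- c(rep(TRUE, scheme$m), rep(FALSE, scheme$n))
  active <- rep(TRUE, length(life))
  w <- numeric(k); z <- integer(k); s <- integer(k); t <- integer(k)
  for (i in seq_len(k)) {
    idx <- which(active)
    # stable min: which.min returns the first index, and line-1 units come first
    fail <- idx[which.min(life[idx])]
    w[i] <- life[fail]; z[i] <- as.integer(line1[fail])
    active[fail] <- FALSE
    Ri <- scheme$R[i]
    if (Ri > 0) {
      surv <- which(active)
      drop <- if (length(surv) == 1) surv else sample(surv, Ri)
      active[drop] <- FALSE
      s[i] <- sum(line1[drop]); t[i] <- Ri - s[i]
    }
  }
  if (any(diff(w) <= 0)) {
    # tied observed failure times (rounded data): nudge by the smallest
    # representable step so the container's strict ordering holds
    w <- cummax(w) + cumsum(duplicated(cummax(w))) * .Machine$double.eps * max(w)
  }
  jpc_sample(w, z, s, t, scheme)
}
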