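#' Conditional moments of withdrawn lifetimes
#'
#' Building block of the E-step.  A unit withdrawn at failure time `w` has an
#' unobserved lifetime `U > w` whose conditional density is the GIED density
#' truncated at `w`.  This function computes, by adaptive quadrature,
#' \deqn{E[\ln U \mid U > w], \quad E[1/U \mid U > w], \quad
#'       E[\ln(1 - e^{-\lambda_{eval}/U}) \mid U > w],}
#' where the conditioning distribution has parameters (`theta`, `lambda`)
#' and the last moment may be evaluated at a different `lambda_eval` (needed
#' when the M-step searches over candidate values of the shared parameter).
#'
#' The quadrature uses the probability-integral substitution
#' \eqn{v = (1-e^{-\lambda/u})^{\theta}}: given `U > w`, `v` is uniform on
#' \eqn{(0, (1-e^{-\lambda/w})^{\theta})}, so every integral is over a
#' bounded interval and the integrands are at worst logarithmically singular
#' at 0, which `stats::integrate` handles.  At `lambda_eval == lambda` the
#' third moment has the closed form \eqn{\ln(1-e^{-\lambda/w}) - 1/\theta},
#' used as an independent check in the tests (the function always
#' integrates).
#'
#' @param theta,lambda parameters of the conditioning GIED.
#' @param w truncation point(s), positive.
#' @param lambda_eval value of \eqn{\lambda} inside the
#'   \eqn{\ln(1-e^{-\lambda/U})} moment; defaults to `lambda`.
#' @return A data.frame with one row per `w`: columns `e_log_u`, `e_inv_u`,
#'   `e_log1mexp`.
#' @export
gied_censored_moments <- function(theta, lambda, w, lambda_eval = lambda) {
  stop_if_not_positive(theta = theta, lambda = lambda, lambda_eval = lambda_eval)
  check_gied_x(w)
  one <- function(wi) {
    cc <- exp(theta * log1mexp(lambda / wi))
    u_of_v <- function(v) lambda / (-log1p(-v^(1 / theta)))
    tmean <- function(h) {
      stats::integrate(function(v) h(u_of_v(v)), 0, cc,
                       rel.tol = 1e-10, abs.tol = 1e-12,
                       subdivisions = 500L)$value / cc
    }
    c(e_log_u = tmean(function(u) log(u)),
      e_inv_u = tmean(function(u) 1 / u),
      e_log1mexp = tmean(function(u) log1mexp(lambda_eval / u)))
  }
  out <- t(vapply(w, one, numeric(3)))
  as.data.frame(out)
}

# single truncated moment E[h(U) | U > w], same substitution as above;
# used in the EM inner loop where only one moment is needed per call
trunc_moment <- function(theta, lambda, w, h) {
  vapply(w, function(wi) {
    cc <- exp(theta * log1mexp(lambda / wi))
    stats::integrate(function(v) h(lambda / (-log1p(-v^(1 / theta)))), 0, cc,
                     rel.tol = 1e-9, abs.tol = 1e-12,
                     subdivisions = 500L)$value / cc
  }, numeric(1))
}

#' E-step expectations for a JPC sample
#'
#' Evaluates the conditional moments of [gied_censored_moments()] at every
#' failure index with withdrawals, for both lines, at the current parameter
#' value.  Rows with `s[i] == 0` (line 1) or `t[i] == 0` (line 2) carry `NA`.
#'
#' @param theta1,theta2,lambda current parameter values.
#' @param data a [jpc_sample].
#' @param lambda_eval see [gied_censored_moments()].
#' @return A list with data.frames `U` (line 1) and `V` (line 2), each with
#'   `k` rows and the three moment columns.
#' @export
jgied_estep <- function(theta1, theta2, lambda, data, lambda_eval = lambda) {
  stopifnot(inherits(data, "jpc_sample"))
  k <- data$scheme$k
  blank <- data.frame(e_log_u = rep(NA_real_, k), e_inv_u = NA_real_,
                      e_log1mexp = NA_real_)
  U <- blank; V <- blank
  iu <- which(data$s > 0); iv <- which(data$t > 0)
  if (length(iu)) U[iu, ] <- gied_censored_moments(theta1, lambda, data$w[iu], lambda_eval)
  if (length(iv)) V[iv, ] <- gied_censored_moments(theta2, lambda, data$w[iv], lambda_eval)
  list(U = U, V = V)
}

# one EM run; returns list(par, loglik, iterations, converged, trace)
em_fit <- function(data, init, tol = 1e-4, max_iter = 500L) {
  check_k1k2(data)
  w <- data$w; z <- data$z; s <- data$s; t <- data$t
  m <- data$scheme$m; n <- data$scheme$n
  iu <- which(s > 0); iv <- which(t > 0)
  th1 <- init[["theta1"]]; th2 <- init[["theta2"]]; lam <- init[["lambda"]]
  trace <- matrix(NA_real_, max_iter, 3,
                  dimnames = list(NULL, c("theta1", "theta2", "lambda")))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step at current parameters: moments not involving the candidate lambda
    inv_u <- if (length(iu)) trunc_moment(th1, lam, w[iu], function(u) 1 / u) else numeric(0)
    inv_v <- if (length(iv)) trunc_moment(th2, lam, w[iv], function(u) 1 / u) else numeric(0)
    Csum <- sum(1 / w) + sum(s[iu] * inv_u) + sum(t[iv] * inv_v)
    # CM-step over lambda: expected complete-data log-likelihood as a function
    # of the candidate value, censored log-terms re-integrated at each point
    Q <- function(lp) {
      eU <- if (length(iu)) trunc_moment(th1, lam, w[iu], function(u) log1mexp(lp / u)) else numeric(0)
      eV <- if (length(iv)) trunc_moment(th2, lam, w[iv], function(u) log1mexp(lp / u)) else numeric(0)
      (m + n) * log(lp) - lp * Csum +
        (th1 - 1) * sum(s[iu] * eU) + (th2 - 1) * sum(t[iv] * eV) +
        sum((z * th1 + (1 - z) * th2 - 1) * log1mexp(lp / w))
    }
    hi <- max(2 * lam, 1)
    expand <- 0L
    while (expand < 60L && Q(hi) > Q(hi * 0.5)) { hi <- 2 * hi; expand <- expand + 1L }
    lam_new <- stats::optimize(Q, c(1e-8, hi), maximum = TRUE, tol = 1e-9)$maximum
    # fresh E-step at (th1, th2, lambda_new), then closed-form CM-step for the
    # exponents: conditioning the latent lifetimes at lambda_new makes this a
    # genuine E-then-CM cycle, so the observed log-likelihood cannot decrease
    A <- log1mexp(lam_new / w)
    eU <- if (length(iu)) trunc_moment(th1, lam_new, w[iu], function(u) log1mexp(lam_new / u)) else numeric(0)
    eV <- if (length(iv)) trunc_moment(th2, lam_new, w[iv], function(u) log1mexp(lam_new / u)) else numeric(0)
    th1_new <- -m / (sum(s[iu] * eU) + sum(z * A))
    th2_new <- -n / (sum(t[iv] * eV) + sum((1 - z) * A))
    trace[it, ] <- c(th1_new, th2_new, lam_new)
    done <- all(abs(c(th1_new - th1, th2_new - th2, lam_new - lam)) <= tol)
    th1 <- th1_new; th2 <- th2_new; lam <- lam_new
    if (done) { converged <- TRUE; break }
  }
  list(par = c(theta1 = th1, theta2 = th2, lambda = lam),
       loglik = jgied_loglik(th1, th2, lam, data),
       iterations = it, converged = converged,
       trace = trace[seq_len(it), , drop = FALSE])
}
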