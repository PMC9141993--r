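#' Observed-data log-likelihood of the two-line GIED model
#'
#' Log-likelihood (up to the scheme's normalizing constant, which does not
#' involve the parameters) of a JPC sample when line 1 is GIED(`theta1`,
#' `lambda`) and line 2 is GIED(`theta2`, `lambda`):
#' \deqn{\ell = k_1\ln\theta_1 + k_2\ln\theta_2 + k\ln\lambda
#'  + \sum_i [\theta_1 s_i + \theta_2 t_i + z_i\theta_1 + (1-z_i)\theta_2 - 1]
#'    \ln(1 - e^{-\lambda/w_i})
#'  - \sum_i [2\ln w_i + \lambda/w_i].}
#'
#' @param theta1,theta2,lambda positive model parameters.
#' @param data a [jpc_sample].
#' @return The log-likelihood value.
#' @seealso [jgied_profile_theta()], [jgied_fit()]
#' @export
jgied_loglik <- function(theta1, theta2, lambda, data) {
  stop_if_not_positive(theta1 = theta1, theta2 = theta2, lambda = lambda)
  stopifnot(inherits(data, "jpc_sample"))
  w <- data$w; z <- data$z; s <- data$s; t <- data$t
  A <- log1mexp(lambda / w)
  data$k1 * log(theta1) + data$k2 * log(theta2) + data$scheme$k * log(lambda) +
    sum((theta1 * s + theta2 * t + z * theta1 + (1 - z) * theta2 - 1) * A) -
    sum(2 * log(w) + lambda / w)
}

#' Profile maximizers and profile log-likelihood over lambda
#'
#' For fixed `lambda` the log-likelihood is concave in
#' \eqn{(\theta_1, \theta_2)} and maximized in closed form:
#' \deqn{\hat\theta_1(\lambda) = -k_1 / M(\lambda), \qquad
#'       \hat\theta_2(\lambda) = -k_2 / N(\lambda),}
#' with \eqn{M(\lambda) = \sum_i (z_i + s_i)\ln(1-e^{-\lambda/w_i})} and
#' \eqn{N(\lambda) = \sum_i (1 - z_i + t_i)\ln(1-e^{-\lambda/w_i})}.
#' `jgied_profile_loglik` plugs these back into the log-likelihood, leaving a
#' one-dimensional function of `lambda` which is unimodal, so the full MLE is
#' found by a single bounded search.  When no failure is observed on one of
#' the lines (`k1 == 0` or `k2 == 0`) the likelihood is monotone in the
#' corresponding exponent and no MLE exists; this is reported as an error of
#' class `"jgied_no_mle"`.
#'
#' With `restricted = TRUE` the maximization respects the order
#' \eqn{\theta_1 < \theta_2}: see [jgied_restricted_theta()].
#'
#' @param lambda positive value of the profiled-out parameter.
#' @param data a [jpc_sample].
#' @param restricted logical; profile under the constraint
#'   \eqn{\theta_1 \le \theta_2}.
#' @return `jgied_profile_theta`: named vector `c(theta1, theta2)`.
#'   `jgied_profile_loglik`: the profile log-likelihood value.
#' @export
jgied_profile_theta <- function(lambda, data) {
  stop_if_not_positive(lambda = lambda)
  stopifnot(inherits(data, "jpc_sample"))
  check_k1k2(data)
  A <- log1mexp(lambda / data$w)
  M <- sum((data$z + data$s) * A)
  N <- sum((1 - data$z + data$t) * A)
  c(theta1 = -data$k1 / M, theta2 = -data$k2 / N)
}

#' @rdname jgied_profile_theta
#' @export
jgied_profile_loglik <- function(lambda, data, restricted = FALSE) {
  th <- if (restricted) jgied_restricted_theta(lambda, data)
        else jgied_profile_theta(lambda, data)
  jgied_loglik(th[["theta1"]], th[["theta2"]], lambda, data)
}

check_k1k2 <- function(data) {
  if (data$k1 == 0 || data$k2 == 0) {
    stop(structure(
      class = c("jgied_no_mle", "error", "condition"),
      list(message = paste0(
             "no maximum likelihood estimate exists: every observed failure ",
             "comes from one line (k1 = ", data$k1, ", k2 = ", data$k2, ")"),
           call = NULL)))
  }
  invisible(TRUE)
}

# one-dimensional maximization of the (unimodal) profile log-likelihood.
# The bracket [lo, hi] is expanded geometrically until the maximum is
# interior; unimodality guarantees the expansion test is sound.
maximize_profile <- function(data, restricted = FALSE,
                             lower = 1e-6, upper = 1, max_expand = 60L) {
  f <- function(l) jgied_profile_loglik(l, data, restricted = restricted)
  hi <- upper
  expansions <- 0L
  while (expansions < max_expand && f(hi) > f(hi * 0.5)) {
    hi <- hi * 2
    expansions <- expansions + 1L
  }
  if (expansions == max_expand) {
    stop("profile likelihood still rising after bracket expansion cap")
  }
  opt <- stats::optimize(f, c(lower, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  list(lambda = opt$maximum, value = opt$objective, converged = TRUE)
}
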