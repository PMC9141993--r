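#' Observed Fisher information by the missing-information principle
#'
#' The observed information of a JPC sample is assembled as
#' \deqn{I_o = m I_1 + n I_2 - \Big[\sum_i s_i\, I_{U|w_i}
#'       + \sum_i t_i\, I_{V|w_i}\Big],}
#' complete information of all placed units minus the information lost in
#' the withdrawn ones.  `gied_unit_info` is the expected per-unit
#' information of a complete GIED observation and `gied_missing_info` that
#' of a unit known only to survive past `w` (its conditional, truncated
#' density).  Parameters are ordered \eqn{(\theta_1, \theta_2, \lambda)};
#' a line-1 unit carries no information about \eqn{\theta_2} and vice versa,
#' so the corresponding rows and columns are structurally zero.
#'
#' Entries are expectations of negative second derivatives of the
#' (conditional) log-density; the \eqn{\theta\theta} entry is exactly
#' \eqn{1/\theta^2} and the remaining expectations are computed by adaptive
#' quadrature after the probability-integral substitution
#' \eqn{v = (1-e^{-\lambda/x})^\theta}, which maps the support onto a
#' bounded interval with a bounded integrand.
#'
#' @param theta,lambda GIED parameters of the unit's line.
#' @param which `"theta1"` or `"theta2"`: which exponent slot the unit's
#'   line occupies.
#' @param w truncation point of the withdrawn unit.
#' @param params named vector `c(theta1, theta2, lambda)`.
#' @param data a [jpc_sample].
#'
#' @return `gied_unit_info` and `gied_missing_info`: a symmetric 3x3 matrix.
#'   `jgied_observed_info`: an object of class `"jgied_info"`, a list with
#'   `I1`, `I2` (per-unit complete information), `missing` (summed missing
#'   information), `observed` (\eqn{I_o}), `covariance` (its inverse) and
#'   `se` (square roots of the diagonal).
#' @examples
#' gied_unit_info(2, 1, "theta1")[1, 1]   # 1 / theta^2 = 0.25
#' @export
gied_unit_info <- function(theta, lambda, which = c("theta1", "theta2")) {
  which <- match.arg(which)
  stop_if_not_positive(theta = theta, lambda = lambda)
  # E[g/(xA)] and E[g/(x^2 A^2)] with g = exp(-lambda/x), A = 1 - g,
  # under v = A^theta ~ U(0,1): A = v^(1/theta), g = 1 - A, 1/x = -log(g)/lambda
  e1 <- stats::integrate(function(v) {
    A <- v^(1 / theta); g <- 1 - A; mlg <- -log1p(-A)  # = -log g, stable
    ifelse(g <= 0, 0, g * mlg / (lambda * A))
  }, 0, 1, rel.tol = 1e-10)$value
  e2 <- stats::integrate(function(v) {
    A <- v^(1 / theta); g <- 1 - A; mlg <- -log1p(-A)
    ifelse(g <= 0, 0, g * mlg^2 / (lambda^2 * A^2))
  }, 0, 1, rel.tol = 1e-10)$value
  info_slots(tt = 1 / theta^2, tl = -e1, ll = 1 / lambda^2 + (theta - 1) * e2,
             which = which)
}

#' @rdname gied_unit_info
#' @export
gied_missing_info <- function(theta, lambda, w, which = c("theta1", "theta2")) {
  which <- match.arg(which)
  stop_if_not_positive(theta = theta, lambda = lambda, w = w)
  cc <- exp(theta * log1mexp(lambda / w))
  e1 <- stats::integrate(function(v) {
    A <- v^(1 / theta); g <- 1 - A; mlg <- -log1p(-A)
    ifelse(g <= 0, 0, g * mlg / (lambda * A))
  }, 0, cc, rel.tol = 1e-10)$value / cc
  e2 <- stats::integrate(function(v) {
    A <- v^(1 / theta); g <- 1 - A; mlg <- -log1p(-A)
    ifelse(g <= 0, 0, g * mlg^2 / (lambda^2 * A^2))
  }, 0, cc, rel.tol = 1e-10)$value / cc
  gw <- exp(-lambda / w); Aw <- -expm1(-lambda / w)
  info_slots(tt = 1 / theta^2,
             tl = -e1 + gw / (w * Aw),
             ll = 1 / lambda^2 + (theta - 1) * e2 - theta * gw / (w^2 * Aw^2),
             which = which)
}

info_slots <- function(tt, tl, ll, which) {
  I <- matrix(0, 3, 3,
              dimnames = rep(list(c("theta1", "theta2", "lambda")), 2))
  i <- if (which == "theta1") 1L else 2L
  I[i, i] <- tt; I[i, 3] <- I[3, i] <- tl; I[3, 3] <- ll
  I
}

#' @rdname gied_unit_info
#' @export
jgied_observed_info <- function(params, data) {
  stopifnot(inherits(data, "jpc_sample"))
  th1 <- params[["theta1"]]; th2 <- params[["theta2"]]; lam <- params[["lambda"]]
  sch <- data$scheme
  I1 <- gied_unit_info(th1, lam, "theta1")
  I2 <- gied_unit_info(th2, lam, "theta2")
  miss <- matrix(0, 3, 3, dimnames = dimnames(I1))
  for (i in seq_len(sch$k)) {
    if (data$s[i] > 0) {
      miss <- miss + data$s[i] * gied_missing_info(th1, lam, data$w[i], "theta1")
    }
    if (data$t[i] > 0) {
      miss <- miss + data$t[i] * gied_missing_info(th2, lam, data$w[i], "theta2")
    }
  }
  Io <- sch$m * I1 + sch$n * I2 - miss
  cov <- tryCatch(solve(Io), error = function(e) {
    stop("observed information is singular; the sample may be too small or ",
         "the estimate on the parameter boundary", call. = FALSE)
  })
  structure(list(I1 = I1, I2 = I2, missing = miss, observed = Io,
                 covariance = cov, se = sqrt(pmax(diag(cov), 0))),
            class = "jgied_info")
}

#' @export
print.jgied_info <- function(x, digits = 4, ...) {
  cat("Observed information (missing-information principle):\n")
  print(round(x$observed, digits))
  cat("Standard errors:\n")
  print(round(x$se, digits))
  invisible(x)
}

#' Finite-difference Hessian of the observed log-likelihood
#'
#' Diagnostic companion to [jgied_observed_info()]: the negative numerical
#' Hessian of the observed-data log-likelihood at `params`.  The
#' missing-information assembly uses *expected* per-unit information scaled
#' by the line sizes, an approximation that coincides with this Hessian when
#' nothing is censored and approaches it in large samples otherwise.
#'
#' @inheritParams jgied_observed_info
#' @param eps relative step of the central differences.
#' @return A symmetric 3x3 matrix.
#' @export
jgied_hessian_info <- function(params, data, eps = 1e-5) {
  p0 <- c(params[["theta1"]], params[["theta2"]], params[["lambda"]])
  f <- function(p) jgied_loglik(p[1], p[2], p[3], data)
  h <- pmax(abs(p0), 1) * eps
  H <- matrix(0, 3, 3, dimnames = rep(list(c("theta1", "theta2", "lambda")), 2))
  for (i in 1:3) for (j in i:3) {
    ei <- ej <- numeric(3); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(p0 + ei + ej) - f(p0 + ei - ej) - f(p0 - ei + ej) + f(p0 - ei - ej)) /
      (4 * h[i] * h[j])
  }
  -H
}
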