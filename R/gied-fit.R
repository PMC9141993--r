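#' Fit the GIED to a complete sample
#'
#' Single-population maximum likelihood for complete (uncensored) lifetime
#' data: for fixed `lambda` the exponent has the closed form
#' \eqn{\hat\theta(\lambda) = -n / \sum_i \ln(1 - e^{-\lambda/x_i})}, and
#' the resulting profile is maximized over `lambda` by a bounded search.
#'
#' @param x vector of positive lifetimes (length at least 2).
#' @return Object of class `"gied_fit"`: `coefficients` (named `theta`,
#'   `lambda`), `loglik`, `n`, `data`.  Methods: `print`, `coef`, `logLik`,
#'   `summary` (adds the goodness-of-fit of [gied_ks()]) and `residuals`
#'   (Cox-Snell residuals \eqn{-\ln \hat S(x_i)}, standard-exponential under
#'   a correct fit).
#' @examples
#' jute <- jute_fiber()
#' gied_fit(jute$strength[jute$gauge == "10mm"])
#' @export
gied_fit <- function(x) {
  check_gied_x(x)
  if (length(x) < 2) stop("need at least two observations")
  n <- length(x)
  prof <- function(lambda) {
    A <- sum(log1mexp(lambda / x))
    th <- -n / A
    n * log(th) + n * log(lambda) - lambda * sum(1 / x) - 2 * sum(log(x)) +
      (th - 1) * A
  }
  hi <- 1; expand <- 0L
  while (expand < 60L && prof(hi) > prof(hi * 0.5)) { hi <- 2 * hi; expand <- expand + 1L }
  opt <- stats::optimize(prof, c(1e-8, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  lam <- opt$maximum
  structure(list(coefficients = c(theta = -n / sum(log1mexp(lam / x)),
                                  lambda = lam),
                 loglik = opt$objective, n = n, data = x),
            class = "gied_fit")
}

#' @export
print.gied_fit <- function(x, digits = 4, ...) {
  cat(sprintf("GIED fit, n = %d\n", x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.*f\n", digits, x$loglik))
  invisible(x)
}

#' @export
coef.gied_fit <- function(object, ...) object$coefficients

#' @export
logLik.gied_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
residuals.gied_fit <- function(object, ...) {
  cf <- coef(object)
  -cf[["theta"]] * log1mexp(cf[["lambda"]] / object$data)
}

#' @export
summary.gied_fit <- function(object, ...) {
  cf <- coef(object)
  structure(list(fit = object,
                 ks = gied_ks(object$data, cf[["theta"]], cf[["lambda"]])),
            class = "summary.gied_fit")
}

#' @export
print.summary.gied_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  print(x$ks, digits = digits)
  invisible(x)
}

#' Kolmogorov-Smirnov goodness of fit for the GIED
#'
#' Distance between the empirical distribution of `x` and the fitted GIED
#' cdf.  Two conventions for the empirical cdf are offered:
#' `positions = "mean"` (default) evaluates \eqn{|i/(n+1) - F(x_{(i)})|} at
#' the mean plotting positions, the convention of reliability practice
#' (and the one under which published analyses of the jute-fibre data
#' reproduce); `positions = "ecdf"` gives the classical two-sided statistic
#' \eqn{D = \max_i \max\{|i/n - F(x_{(i)})|, |(i-1)/n - F(x_{(i)})|\}}.
#' The p value is from the asymptotic Kolmogorov distribution at
#' \eqn{\sqrt n D} (approximate: it ignores both parameter estimation and,
#' for `"mean"`, the plotting-position shift) and should be read as a
#' descriptive index of fit.
#'
#' @param x lifetimes.
#' @param theta,lambda fitted GIED parameters.
#' @param positions empirical-cdf convention, see Details.
#' @return Object of class `"gied_ks"`: list with `statistic`, `p.value`,
#'   `n`, `positions`.
#' @examples
#' jute <- jute_fiber()
#' f <- gied_fit(jute$strength[jute$gauge == "10mm"])
#' gied_ks(jute$strength[jute$gauge == "10mm"], coef(f)[1], coef(f)[2])
#' @export
gied_ks <- function(x, theta, lambda, positions = c("mean", "ecdf")) {
  positions <- match.arg(positions)
  check_gied_x(x)
  xs <- sort(x); n <- length(xs); i <- seq_len(n)
  Fx <- pgied(xs, theta, lambda)
  D <- if (positions == "mean") {
    max(abs(i / (n + 1) - Fx))
  } else {
    max(pmax(abs(i / n - Fx), abs(Fx - (i - 1) / n)))
  }
  structure(list(statistic = D, p.value = kolmogorov_pvalue(sqrt(n) * D),
                 n = n, positions = positions),
            class = "gied_ks")
}

# asymptotic Kolmogorov tail: P(sup > z) = 2 sum_{j>=1} (-1)^(j-1) exp(-2 j^2 z^2)
kolmogorov_pvalue <- function(z) {
  if (z <= 0) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * z^2))))
}

#' @export
print.gied_ks <- function(x, digits = 4, ...) {
  cat(sprintf("K-S distance (%s positions): D = %.*f, approx p = %.*f (n = %d)\n",
              x$positions, digits, x$statistic, digits, x$p.value, x$n))
  invisible(x)
}

#' Likelihood-ratio test for a shared lambda across two complete samples
#'
#' Tests whether the two GIED populations share the parameter
#' \eqn{\lambda}.  The alternative fits each sample freely (4 parameters,
#' two [gied_fit()]s); the null fits the joint model with common
#' \eqn{\lambda} and distinct exponents (3 parameters, via [jgied_fit()] on
#' the pooled data treated as an uncensored JPC sample).  The statistic
#' \eqn{2(\ell_1 - \ell_0)} is referred to \eqn{\chi^2_1}.
#'
#' @param x1,x2 complete lifetime vectors.
#' @return Object of class `"gied_lrt"`: `statistic`, `df`, `p.value`,
#'   `null_fit` (the common-lambda [jgied_fit]), `alt_fits` (list of two
#'   [gied_fit]s).
#' @examples
#' jute <- jute_fiber()
#' gied_lrt(jute$strength[jute$gauge == "10mm"],
#'          jute$strength[jute$gauge == "20mm"])
#' @export
gied_lrt <- function(x1, x2) {
  f1 <- gied_fit(x1); f2 <- gied_fit(x2)
  null_fit <- jgied_fit(jpc_complete(x1, x2), method = "profile")
  stat <- 2 * (f1$loglik + f2$loglik - null_fit$loglik)
  structure(list(statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 null_fit = null_fit, alt_fits = list(f1, f2)),
            class = "gied_lrt")
}

#' Pool two complete samples into an uncensored JPC sample
#'
#' Helper for joint fits of complete data: the pooled, sorted observations
#' with line labels form a JPC sample with all withdrawals zero and
#' `k = m + n`.
#'
#' @param x1,x2 complete lifetime vectors for the two lines.
#' @return A [jpc_sample].
#' @export
jpc_complete <- function(x1, x2) {
  sch <- jpc_scheme(length(x1), length(x2), length(x1) + length(x2),
                    rep(0L, length(x1) + length(x2)))
  jpc_censor(x1, x2, sch)
}

#' @export
print.gied_lrt <- function(x, digits = 4, ...) {
  cat("Likelihood-ratio test of a common lambda\n")
  cat(sprintf("  LR statistic = %.*f on %d df, p = %.*f\n",
              digits, x$statistic, x$df, digits, x$p.value))
  cat("  common-lambda MLEs:\n")
  print(round(coef(x$null_fit), digits))
  invisible(x)
}
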