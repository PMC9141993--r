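#' Fit the two-line GIED model to a JPC sample
#'
#' Maximum likelihood estimation of \eqn{(\theta_1, \theta_2, \lambda)} from
#' a joint progressively type-II censored sample, either by direct
#' maximization of the one-dimensional profile likelihood over `lambda`
#' (`method = "profile"`, the default: the profile is unimodal, so a bounded
#' search with an auto-expanded bracket finds the global maximum) or by an
#' expectation-maximization algorithm treating the withdrawn units'
#' lifetimes as missing data (`method = "em"`).  Both methods solve the same
#' maximization and agree to optimizer tolerance; the EM route is the one
#' used in the reliability literature for this design and exposes the
#' iteration trace.
#'
#' With `order_restricted = TRUE` the estimate obeys
#' \eqn{\theta_1 \le \theta_2}: the restricted profile (see
#' [jgied_restricted_theta()]) is maximized over `lambda` — this path always
#' uses the profile search, as the restricted EM variant is not defined.
#'
#' The EM iteration stops when every coordinate changes by at most `tol`
#' (the customary 0.0001).  The default initial value maximizes the profile
#' log-likelihood on a coarse 20-point logarithmic grid for `lambda` with the
#' closed-form exponents plugged in; `init` overrides it.
#'
#' No MLE exists when all observed failures come from a single line
#' (`k1 == 0` or `k2 == 0`); an error of class `"jgied_no_mle"` is raised.
#'
#' @param data a [jpc_sample].
#' @param method `"profile"` or `"em"`.
#' @param order_restricted logical; impose \eqn{\theta_1 \le \theta_2}.
#' @param init optional named vector `c(theta1=, theta2=, lambda=)` used to
#'   start the EM iteration.
#' @param tol EM stopping tolerance on absolute per-coordinate changes.
#' @param max_iter maximum number of EM iterations (non-convergence is
#'   flagged in the result, not raised).
#'
#' @return An object of class `"jgied_fit"` with components `coefficients`
#'   (named vector `theta1`, `theta2`, `lambda`), `loglik`, `method`,
#'   `iterations`, `converged`, `trace` (EM only), `order_restricted`,
#'   `on_boundary` (restricted fits), and `data`.
#'   Methods: [print()], [summary()] (adds standard errors from the observed
#'   information), [coef()], [logLik()], [vcov()] (inverse observed
#'   information, see [jgied_observed_info()]), [confint()] (percentile
#'   bootstrap, see [jgied_boot()]) and [simulate()] (parametric re-draws
#'   under the fitted model and the same scheme).
#'
#' @examples
#' sch <- jpc_scheme(20, 25, 20, "(0(4),25,0(15))")
#' set.seed(11)
#' d <- rjpc(sch, theta1 = 1, theta2 = 1, lambda = 0.5)
#' fit <- jgied_fit(d)
#' coef(fit)
#' logLik(fit)
#' @export
jgied_fit <- function(data, method = c("profile", "em"),
                      order_restricted = FALSE, init = NULL,
                      tol = 1e-4, max_iter = 500L) {
  stopifnot(inherits(data, "jpc_sample"))
  method <- match.arg(method)
  check_k1k2(data)
  if (order_restricted) {
    opt <- maximize_profile(data, restricted = TRUE)
    th <- jgied_restricted_theta(opt$lambda, data)
    res <- list(coefficients = c(theta1 = th[["theta1"]],
                                 theta2 = th[["theta2"]],
                                 lambda = opt$lambda),
                loglik = opt$value, method = "profile",
                iterations = 0L, converged = TRUE, trace = NULL,
                order_restricted = TRUE,
                on_boundary = isTRUE(attr(th, "on_boundary")),
                data = data, call = match.call())
    return(structure(res, class = "jgied_fit"))
  }
  if (method == "profile") {
    opt <- maximize_profile(data)
    th <- jgied_profile_theta(opt$lambda, data)
    out <- list(par = c(th, lambda = opt$lambda), loglik = opt$value,
                iterations = 0L, converged = opt$converged, trace = NULL)
  } else {
    if (is.null(init)) init <- default_init(data)
    out <- em_fit(data, init, tol = tol, max_iter = max_iter)
  }
  structure(list(coefficients = out$par, loglik = out$loglik, method = method,
                 iterations = out$iterations, converged = out$converged,
                 trace = out$trace, order_restricted = FALSE,
                 on_boundary = FALSE, data = data, call = match.call()),
            class = "jgied_fit")
}

# coarse profile grid for the EM starting value
default_init <- function(data) {
  grid <- exp(seq(log(1e-3), log(50), length.out = 20))
  vals <- vapply(grid, jgied_profile_loglik, numeric(1), data = data)
  lam0 <- grid[which.max(vals)]
  th0 <- jgied_profile_theta(lam0, data)
  c(theta1 = th0[["theta1"]], theta2 = th0[["theta2"]], lambda = lam0)
}

#' @export
print.jgied_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-line GIED fit under joint progressive type-II censoring (%s)\n",
              if (x$order_restricted) "order-restricted" else x$method))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.*f\n", digits, x$loglik))
  if (x$order_restricted && x$on_boundary) {
    cat("estimate on the boundary theta1 = theta2\n")
  }
  if (x$method == "em") {
    cat(sprintf("EM iterations: %d (%s)\n", x$iterations,
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
coef.jgied_fit <- function(object, ...) object$coefficients

#' @export
logLik.jgied_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$on_boundary) 2L else 3L,
            nobs = object$data$scheme$k, class = "logLik")
}

#' @export
vcov.jgied_fit <- function(object, ...) {
  jgied_observed_info(coef(object), object$data)$covariance
}

#' @export
summary.jgied_fit <- function(object, ...) {
  se <- tryCatch(sqrt(diag(vcov(object))), error = function(e) rep(NA_real_, 3))
  tab <- cbind(Estimate = coef(object), `Std. Error` = se)
  structure(list(fit = object, coefficients = tab), class = "summary.jgied_fit")
}

#' @export
print.summary.jgied_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
confint.jgied_fit <- function(object, parm, level = 0.95, B = 1000, ...) {
  ci <- jgied_boot(object, B = B, level = level)$intervals
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
simulate.jgied_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- coef(object)
  replicate(nsim,
            rjpc(object$data$scheme, cf[["theta1"]], cf[["theta2"]], cf[["lambda"]]),
            simplify = FALSE)
}
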