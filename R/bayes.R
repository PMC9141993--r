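#' Gamma prior specification
#'
#' Independent Gamma priors \eqn{\theta_1 \sim Ga(a_1, b_1)},
#' \eqn{\theta_2 \sim Ga(a_2, b_2)}, \eqn{\lambda \sim Ga(c, d)}
#' (shape/rate).  The default sets every hyper-parameter to `1e-5`, the
#' customary near-flat "non-informative" choice for this model.
#'
#' @param a1,b1,a2,b2,c,d positive hyper-parameters.
#' @return An object of class `"jgied_prior"`.
#' @examples
#' jgied_prior()                                   # non-informative
#' jgied_prior(a1 = 2, b1 = 1, a2 = 1, b2 = 2, c = 3, d = 2)  # informative
#' @export
jgied_prior <- function(a1 = 1e-5, b1 = 1e-5, a2 = 1e-5, b2 = 1e-5,
                        c = 1e-5, d = 1e-5) {
  stop_if_not_positive(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c, d = d)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c, d = d),
            class = "jgied_prior")
}

#' @export
print.jgied_prior <- function(x, ...) {
  cat(sprintf("Gamma priors: theta1 ~ Ga(%g, %g), theta2 ~ Ga(%g, %g), lambda ~ Ga(%g, %g)\n",
              x$a1, x$b1, x$a2, x$b2, x$c, x$d))
  invisible(x)
}

#' Posterior sampling components
#'
#' The joint posterior factorizes into tractable Gamma proposals times a
#' weight: \eqn{\lambda \mid data \sim Ga(c + k,\; d + \sum 1/w_i)};
#' given \eqn{\lambda},
#' \eqn{\theta_1 \sim Ga(a_1 + k_1,\; b_1 - \sum (z_i + s_i) A_i)} and
#' \eqn{\theta_2 \sim Ga(a_2 + k_2,\; b_2 - \sum (1 - z_i + t_i) A_i)} with
#' \eqn{A_i = \ln(1 - e^{-\lambda/w_i}) < 0} (so both rates exceed the prior
#' rates); and the importance weight
#' \deqn{d(\lambda) \propto \prod_i (1-e^{-\lambda/w_i})^{-1}
#'   \cdot r_1(\lambda)^{-(a_1+k_1)} \cdot r_2(\lambda)^{-(a_2+k_2)},}
#' which does not involve the exponents.
#'
#' @param data a [jpc_sample].
#' @param prior a [jgied_prior].
#' @return A list: `lambda` (c(shape, rate)), `theta1_shape`, `theta2_shape`,
#'   and functions `theta1_rate(lambda)`, `theta2_rate(lambda)`,
#'   `log_weight(lambda)` (vectorized, up to an additive constant).
#' @export
jgied_posterior_components <- function(data, prior = jgied_prior()) {
  stopifnot(inherits(data, "jpc_sample"), inherits(prior, "jgied_prior"))
  w <- data$w; z <- data$z; s <- data$s; t <- data$t
  k <- data$scheme$k; k1 <- data$k1; k2 <- data$k2
  sh1 <- prior$a1 + k1; sh2 <- prior$a2 + k2
  rate1 <- function(lambda) {
    vapply(lambda, function(l) prior$b1 - sum((z + s) * log1mexp(l / w)),
           numeric(1))
  }
  rate2 <- function(lambda) {
    vapply(lambda, function(l) prior$b2 - sum((1 - z + t) * log1mexp(l / w)),
           numeric(1))
  }
  log_weight <- function(lambda) {
    vapply(lambda, function(l) {
      -sum(log1mexp(l / w)) - sh1 * log(prior$b1 - sum((z + s) * log1mexp(l / w))) -
        sh2 * log(prior$b2 - sum((1 - z + t) * log1mexp(l / w)))
    }, numeric(1))
  }
  list(lambda = c(shape = prior$c + k, rate = prior$d + sum(1 / w)),
       theta1_shape = sh1, theta2_shape = sh2,
       theta1_rate = rate1, theta2_rate = rate2, log_weight = log_weight)
}

#' Importance-sampling Bayesian inference for the JPC GIED model
#'
#' Draws `M` posterior triples \eqn{(\theta_1, \theta_2, \lambda)} by
#' importance sampling from the Gamma proposal decomposition of
#' [jgied_posterior_components()], with all weight arithmetic in log space.
#' With `order_restricted = TRUE` the prior is the symmetrized two-component
#' Gamma mixture restricted to \eqn{\theta_1 < \theta_2}: draws come from
#' the unrestricted mixture (component weights proportional to their
#' normalizing constants at the drawn \eqn{\lambda}) and draws violating the
#' order get weight zero.
#'
#' Point estimates are posterior means under squared-error loss (SEL) or the
#' linex rule \eqn{-h^{-1}\ln E[e^{-h\omega} \mid data]} (see
#' [coef.jgied_bayes()]); credible intervals are symmetric-tail weighted
#' quantiles (see [confint.jgied_bayes()]).
#'
#' @param data a [jpc_sample].
#' @param prior a [jgied_prior].
#' @param M number of importance draws.
#' @param order_restricted logical; impose \eqn{\theta_1 < \theta_2}.
#' @return Object of class `"jgied_bayes"`: list with `draws` (M x 3
#'   matrix), `log_weight` (raw, up to a constant), `weights` (normalized),
#'   `ess` (effective sample size \eqn{1/\sum q_i^2}), `M`, `prior`,
#'   `order_restricted`, `data`.
#' @examples
#' sch <- jpc_scheme(10, 10, 12, c(rep(0, 11), 8))
#' set.seed(5)
#' post <- jgied_bayes(rjpc(sch, 1, 1, 0.5), M = 2000)
#' coef(post)                       # SEL estimates
#' coef(post, loss = "linex", h = 2)
#' confint(post, level = 0.90)
#' @export
jgied_bayes <- function(data, prior = jgied_prior(), M = 10000,
                        order_restricted = FALSE) {
  stopifnot(inherits(data, "jpc_sample"), M >= 1)
  pc <- jgied_posterior_components(data, prior)
  lam <- stats::rgamma(M, shape = pc$lambda[["shape"]], rate = pc$lambda[["rate"]])
  r1 <- pc$theta1_rate(lam); r2 <- pc$theta2_rate(lam)
  if (!order_restricted) {
    th1 <- stats::rgamma(M, shape = pc$theta1_shape, rate = r1)
    th2 <- stats::rgamma(M, shape = pc$theta2_shape, rate = r2)
    logw <- pc$log_weight(lam)
  } else {
    a1 <- prior$a1; a2 <- prior$a2; k1 <- data$k1; k2 <- data$k2
    # two components of the symmetrized prior, rates shared
    lZA <- lgamma(a1 + k1) - (a1 + k1) * log(r1) +
           lgamma(a2 + k2) - (a2 + k2) * log(r2)
    lZB <- lgamma(a2 + k1) - (a2 + k1) * log(r1) +
           lgamma(a1 + k2) - (a1 + k2) * log(r2)
    pA <- 1 / (1 + exp(lZB - lZA))
    useA <- stats::runif(M) < pA
    th1 <- stats::rgamma(M, shape = ifelse(useA, a1 + k1, a2 + k1), rate = r1)
    th2 <- stats::rgamma(M, shape = ifelse(useA, a2 + k2, a1 + k2), rate = r2)
    base <- vapply(lam, function(l) -sum(log1mexp(l / data$w)), numeric(1))
    logw <- base + pmax(lZA, lZB) + log1p(exp(-abs(lZA - lZB)))
    logw[th1 >= th2] <- -Inf
    if (all(!is.finite(logw))) {
      stop("no draw satisfied theta1 < theta2; increase M", call. = FALSE)
    }
  }
  lse <- logsumexp(logw)
  q <- exp(logw - lse)
  structure(list(draws = cbind(theta1 = th1, theta2 = th2, lambda = lam),
                 log_weight = logw, weights = q, ess = 1 / sum(q^2),
                 M = M, prior = prior, order_restricted = order_restricted,
                 data = data),
            class = "jgied_bayes")
}

#' Bayes point estimates from an importance sample
#'
#' Under squared-error loss the estimate of an estimand \eqn{g} is the
#' weighted posterior mean \eqn{\sum_i q_i g_i}; under linex loss with
#' constant `h` it is \eqn{-h^{-1}\ln \sum_i q_i e^{-h g_i}} (computed by
#' log-sum-exp).  `coef()` applies this to the three parameters;
#' `jgied_bayes_estimate()` to an arbitrary function of the draws.
#'
#' @param object a [jgied_bayes] object.
#' @param loss `"sel"` or `"linex"`.
#' @param h linex asymmetry constant (must be nonzero; `h = 2` is the
#'   customary choice).
#' @param g function of `(theta1, theta2, lambda)` returning a scalar, or a
#'   numeric vector of length `M` of precomputed estimand values.
#' @param ... unused.
#' @return Named numeric vector (for `coef`) or scalar.
#' @export
coef.jgied_bayes <- function(object, loss = c("sel", "linex"), h = 2, ...) {
  loss <- match.arg(loss)
  vapply(c(theta1 = "theta1", theta2 = "theta2", lambda = "lambda"),
         function(p) jgied_bayes_estimate(object, object$draws[, p], loss, h),
         numeric(1))
}

#' @rdname coef.jgied_bayes
#' @export
jgied_bayes_estimate <- function(object, g, loss = c("sel", "linex"), h = 2) {
  loss <- match.arg(loss)
  gv <- if (is.function(g)) {
    apply(object$draws, 1, function(r) g(r[[1]], r[[2]], r[[3]]))
  } else g
  stopifnot(length(gv) == object$M)
  if (loss == "sel") return(sum(object$weights * gv))
  if (h == 0) stop("linex loss needs h != 0; use loss = \"sel\" for h = 0")
  lq <- log(object$weights)
  -logsumexp(lq - h * gv) / h
}

#' Symmetric credible intervals from an importance sample
#'
#' Sorts the estimand over the draws (stably, ties by draw index), carries
#' the normalized weights along, and returns the window of draws whose
#' enclosed posterior mass does not exceed `level` while adding one more
#' draw would exceed it, choosing among such windows the one with the most
#' balanced tail masses.  With uniform weights this reduces to the usual
#' percentile rule up to one order statistic.
#'
#' @param object a [jgied_bayes] object.
#' @param parm parameters to report (default all three).
#' @param level credible level.
#' @param ... unused.
#' @return Matrix with one row per parameter, columns lower/upper.
#' @export
confint.jgied_bayes <- function(object, parm, level = 0.90, ...) {
  pars <- c("theta1", "theta2", "lambda")
  if (!missing(parm)) pars <- pars[match(parm, pars, nomatch = 0)]
  out <- t(vapply(pars, function(p) {
    sym_cred_interval(object$draws[, p], object$weights, level)
  }, numeric(2)))
  zeta <- 1 - level
  colnames(out) <- sprintf("%g %%", 100 * c(zeta / 2, 1 - zeta / 2))
  out
}

# weighted symmetric-tail interval: enumerate windows (n1, n2) of the sorted
# sample with mass(n1..n2) <= level < mass(n1..n2+1), take the most
# tail-balanced one
sym_cred_interval <- function(g, q, level) {
  ord <- order(g)           # stable: ties keep draw order
  gs <- g[ord]; qs <- q[ord]
  M <- length(gs)
  cq <- cumsum(qs)
  tol <- 1e-12
  best <- NULL; best_asym <- Inf
  n2 <- 1L
  for (n1 in seq_len(M)) {
    if (n2 < n1) n2 <- n1
    lower_mass <- if (n1 == 1L) 0 else cq[n1 - 1L]
    while (n2 + 1L <= M && cq[n2 + 1L] - lower_mass <= level + tol) n2 <- n2 + 1L
    if (n2 >= M) break  # no (n2 + 1)-th draw to exceed the level
    mass <- cq[n2] - lower_mass
    if (mass <= level + tol) {
      asym <- abs(lower_mass - (1 - cq[n2]))
      if (asym < best_asym - tol) { best <- c(n1, n2); best_asym <- asym }
    }
  }
  if (is.null(best)) {  # degenerate weights: fall back to weighted quantiles
    lo <- gs[which(cq >= (1 - level) / 2)[1]]
    hi <- gs[which(cq >= 1 - (1 - level) / 2)[1]]
    return(c(lo, hi))
  }
  c(gs[best[1]], gs[best[2]])
}

#' @export
print.jgied_bayes <- function(x, digits = 4, ...) {
  cat(sprintf("Importance-sampling posterior (%sM = %d draws, ESS = %.0f)\n",
              if (x$order_restricted) "order-restricted, " else "", x$M, x$ess))
  cat("SEL estimates:\n")
  print(round(coef(x), digits))
  if (x$ess < 0.05 * x$M) {
    cat("note: effective sample size below 5% of M; weights are unstable\n")
  }
  invisible(x)
}
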