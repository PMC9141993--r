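#' Order-restricted profile maximizers
#'
#' Profile maximizers of the exponents under the order restriction
#' \eqn{\theta_1 \le \theta_2} (line 1 stochastically stronger).  Because the
#' log-likelihood is concave in \eqn{(\theta_1, \theta_2)} at fixed
#' `lambda`, the restricted maximizer either coincides with the unrestricted
#' one (when \eqn{\hat\theta_1(\lambda) < \hat\theta_2(\lambda)}) or lies on
#' the boundary \eqn{\theta_1 = \theta_2}, where the common value has the
#' pooled closed form
#' \deqn{\tilde\theta(\lambda) =
#'   -k \big/ \sum_{i=1}^k (R_i + 1)\ln(1 - e^{-\lambda/w_i}),}
#' the unique positive stationary point of the log-likelihood along the
#' diagonal.
#'
#' @inheritParams jgied_profile_theta
#' @return Named vector `c(theta1, theta2)` with attribute `on_boundary`
#'   (logical).
#' @seealso [jgied_fit()] with `order_restricted = TRUE`.
#' @export
jgied_restricted_theta <- function(lambda, data) {
  th <- jgied_profile_theta(lambda, data)
  if (th[["theta1"]] < th[["theta2"]]) {
    attr(th, "on_boundary") <- FALSE
    return(th)
  }
  A <- log1mexp(lambda / data$w)
  pooled <- -data$scheme$k / sum((data$scheme$R + 1) * A)
  structure(c(theta1 = pooled, theta2 = pooled), on_boundary = TRUE)
}
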