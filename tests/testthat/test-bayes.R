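test_that("posterior components on the toy sample", {
  toy <- toy_sample()
  pr <- jgied_prior(a1 = 1, b1 = 1, a2 = 1, b2 = 1, c = 1, d = 1)
  pc <- jgied_posterior_components(toy, pr)
  # lambda proposal: Gamma(c + k, d + sum 1/w) = Gamma(3, 1 + 1 + 0.5)
  expect_equal(unname(pc$lambda), c(3, 2.5))
  expect_equal(pc$theta1_shape, 2)   # a1 + k1
  expect_equal(pc$theta2_shape, 2)
  # conditional rates exceed the prior rates for every lambda
  for (l in c(0.1, 1, 10)) {
    expect_gt(pc$theta1_rate(l), pr$b1)
    expect_gt(pc$theta2_rate(l), pr$b2)
  }
  # rates are b - (z + s) %*% A and b - (1 - z + t) %*% A
  A <- log1mexp_pkg(1 / toy$w)
  expect_equal(pc$theta1_rate(1), 1 - 2 * A[1], tolerance = 1e-12)
  expect_equal(pc$theta2_rate(1), 1 - 2 * A[2], tolerance = 1e-12)
})

test_that("the importance sampler is reproducible and marginally correct", {
  set.seed(173)
  d <- draw_valid_jpc(small_scheme(), 1, 1, 0.5)
  set.seed(179); a <- jgied_bayes(d, M = 500)
  set.seed(179); b <- jgied_bayes(d, M = 500)
  expect_identical(a$draws, b$draws)
  expect_identical(a$weights, b$weights)
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)

  # lambda draws come from their Gamma proposal
  set.seed(181)
  post <- jgied_bayes(d, M = 10000)
  pc <- jgied_posterior_components(d, jgied_prior())
  ks <- suppressWarnings(stats::ks.test(post$draws[, "lambda"], "pgamma",
                                        pc$lambda[["shape"]], pc$lambda[["rate"]]))
  expect_gt(ks$p.value, 0.001)
  expect_true(post$ess > 1 && post$ess <= post$M)
})

test_that("SEL and linex estimates obey their limiting relations", {
  set.seed(191)
  d <- draw_valid_jpc(small_scheme(), 1, 1, 0.5)
  post <- jgied_bayes(d, M = 2000)
  g <- post$draws[, "lambda"]
  # uniform weights: SEL reduces to the plain mean
  uni <- post; uni$weights <- rep(1 / post$M, post$M)
  expect_equal(jgied_bayes_estimate(uni, g, "sel"), mean(g), tolerance = 1e-12)
  # linex -> SEL as h -> 0
  sel <- coef(post)
  lin0 <- coef(post, loss = "linex", h = 1e-5)
  expect_equal(lin0, sel, tolerance = 1e-4)
  # Jensen: linex with h > 0 never exceeds SEL
  lin2 <- coef(post, loss = "linex", h = 2)
  expect_true(all(lin2 <= sel + 1e-12))
  expect_error(coef(post, loss = "linex", h = 0), "h != 0")
})

test_that("credible windows implement the symmetric-tail rule", {
  # 4-draw case solved by enumerating all admissible windows by hand
  ci <- jointGIED:::sym_cred_interval(c(1, 2, 3, 4), c(0.1, 0.4, 0.4, 0.1), 0.80)
  expect_equal(ci, c(2, 3))
  # uniform weights: agrees with the percentile rule up to one order statistic
  set.seed(193)
  g <- sort(rnorm(1000))
  ci_u <- jointGIED:::sym_cred_interval(g, rep(1 / 1000, 1000), 0.90)
  expect_true(ci_u[1] %in% g[50:51])
  expect_true(ci_u[2] %in% g[950:951])
})

test_that("credible intervals usually cover the SEL point estimate", {
  set.seed(197)
  hits <- replicate(20, {
    d <- draw_valid_jpc(small_scheme(), 1, 1, 0.5)
    post <- jgied_bayes(d, M = 1000)
    ci <- confint(post, level = 0.90)
    sel <- coef(post)
    all(ci[, 1] <= sel & sel <= ci[, 2])
  })
  expect_gte(mean(hits), 0.9)   # advisory property, not a theorem
})

test_that("a concentrated prior dominates the data", {
  set.seed(199)
  d <- draw_valid_jpc(small_scheme(), 1, 1, 0.5)
  pr <- jgied_prior(a1 = 3e6, b1 = 1e6)   # theta1 pinned near 3
  post <- jgied_bayes(d, prior = pr, M = 4000)
  expect_equal(coef(post)[["theta1"]], 3, tolerance = 0.01 * 3)
})

test_that("the non-informative posterior tracks the MLE on complete data", {
  set.seed(211)
  sch <- jpc_scheme(20, 25, 45, rep(0L, 45))
  d <- jpc_censor(rgied(20, 1, 0.5), rgied(25, 1, 0.5), sch)
  mle <- coef(jgied_fit(d))
  post <- jgied_bayes(d, M = 10000)
  expect_lt(max(abs(coef(post) - mle)), 0.1)   # advisory closeness
})

test_that("order-restricted sampling enforces the constraint coherently", {
  toy <- toy_sample()
  pr <- jgied_prior(a1 = 1, b1 = 1, a2 = 1, b2 = 1, c = 1, d = 1)
  set.seed(223)
  post <- jgied_bayes(toy, prior = pr, M = 20000, order_restricted = TRUE)
  live <- post$weights > 0
  expect_true(all(post$draws[live, "theta1"] < post$draws[live, "theta2"]))

  # with a1 = a2, b1 = b2 the mixture components coincide and the posterior
  # mass on theta1 < theta2 matches a nested-quadrature oracle
  pc <- jgied_posterior_components(toy, pr)
  p_given_lam <- function(l) {
    r1 <- pc$theta1_rate(l); r2 <- pc$theta2_rate(l)
    stats::integrate(function(u) stats::dgamma(u, 2, rate = r1) *
                       stats::pgamma(u, 2, rate = r2, lower.tail = FALSE),
                     0, Inf, rel.tol = 1e-9)$value
  }
  kern <- function(l) exp(stats::dgamma(l, pc$lambda[["shape"]],
                                        rate = pc$lambda[["rate"]], log = TRUE) +
                          pc$log_weight(l))
  num <- stats::integrate(function(l) vapply(l, function(li)
    kern(li) * p_given_lam(li), numeric(1)), 0, Inf, rel.tol = 1e-8)$value
  den <- stats::integrate(function(l) vapply(l, kern, numeric(1)),
                          0, Inf, rel.tol = 1e-8)$value
  oracle <- num / den
  set.seed(227)
  unres <- jgied_bayes(toy, prior = pr, M = 50000)
  frac <- sum(unres$weights[unres$draws[, "theta1"] < unres$draws[, "theta2"]])
  expect_lt(abs(frac - oracle), 0.02)
})

test_that("restriction is immaterial when the data already order the lines", {
  set.seed(229)
  sch <- jpc_scheme(100, 100, 200, rep(0L, 200))
  d <- jpc_censor(rgied(100, 0.3, 0.5), rgied(100, 3, 0.5), sch)
  set.seed(233); res <- jgied_bayes(d, M = 5000, order_restricted = TRUE)
  set.seed(239); unres <- jgied_bayes(d, M = 5000)
  expect_lt(max(abs(coef(res) - coef(unres))), 0.05)
})
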