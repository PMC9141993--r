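test_that("exact entries and zero patterns of the unit information", {
  I1 <- gied_unit_info(2, 1, "theta1")
  expect_equal(I1[1, 1], 0.25)
  # a line-1 unit says nothing about theta2
  expect_equal(I1[2, ], c(theta1 = 0, theta2 = 0, lambda = 0))
  expect_equal(I1[, 2], c(theta1 = 0, theta2 = 0, lambda = 0))
  expect_identical(I1, t(I1))
  I2 <- gied_unit_info(2, 1, "theta2")
  expect_equal(I2[1, ], c(theta1 = 0, theta2 = 0, lambda = 0))
  expect_equal(I2[2, 2], 0.25)

  Im <- gied_missing_info(2, 1, 0.7, "theta2")
  expect_equal(Im[2, 2], 0.25)   # truncation term is linear in theta
  expect_equal(Im[1, ], c(theta1 = 0, theta2 = 0, lambda = 0))
  expect_identical(Im, t(Im))
})

test_that("quadrature entries match a Monte Carlo finite-difference Hessian", {
  th <- 1.6; lam <- 0.8
  I <- gied_unit_info(th, lam, "theta1")
  set.seed(97)
  x <- rgied(200000, th, lam)
  eps <- 1e-3
  ll <- function(t, l) dgied(x, t, l, log = TRUE)
  entries <- list(
    tt = -(ll(th + eps, lam) - 2 * ll(th, lam) + ll(th - eps, lam)) / eps^2,
    tl = -(ll(th + eps, lam + eps) - ll(th + eps, lam - eps) -
           ll(th - eps, lam + eps) + ll(th - eps, lam - eps)) / (4 * eps^2),
    llm = -(ll(th, lam + eps) - 2 * ll(th, lam) + ll(th, lam - eps)) / eps^2)
  mc <- vapply(entries, mean, numeric(1))
  se <- vapply(entries, function(v) sd(v) / sqrt(length(v)), numeric(1))
  expect_lt(abs(I[1, 1] - mc[["tt"]]), 3 * se[["tt"]] + 1e-6)
  expect_lt(abs(I[1, 3] - mc[["tl"]]), 3 * se[["tl"]] + 1e-6)
  expect_lt(abs(I[3, 3] - mc[["llm"]]), 3 * se[["llm"]] + 1e-5)
})

test_that("missing information converges to unit information as w -> 0", {
  th <- 1.3; lam <- 0.9
  Iu <- gied_unit_info(th, lam, "theta1")
  Im <- gied_missing_info(th, lam, 1e-3 * lam, "theta1")
  expect_equal(Im, Iu, tolerance = 1e-4)
})

test_that("observed information is assembled correctly at the MLE", {
  set.seed(103)
  sch <- jpc_scheme(20, 25, 25, "(0(9),20,0(15))")
  d <- draw_valid_jpc(sch, 1, 1, 0.5)
  fit <- jgied_fit(d)
  info <- jgied_observed_info(coef(fit), d)
  # theta-theta slots carry no missing-vs-complete discrepancy in structure
  expect_equal(info$observed[1, 2], 0)
  expect_identical(info$observed, t(info$observed))
  # covariance positive definite at an interior maximum
  expect_true(all(eigen(info$covariance, symmetric = TRUE)$values > 0))
  expect_equal(sqrt(diag(info$covariance)), info$se, tolerance = 1e-12)
  expect_equal(unname(vcov(fit)), unname(info$covariance))
})

test_that("uncensored samples: expected assembly tracks the observed Hessian", {
  # with R = 0 nothing is missing; I_o = m I1 + n I2 is the expected
  # information, which matches the realized Hessian up to sampling noise,
  # and the theta-theta entries agree exactly (k1 = m, k2 = n)
  set.seed(107)
  m <- 200; n <- 250
  sch <- jpc_scheme(m, n, m + n, rep(0L, m + n))
  d <- jpc_censor(rgied(m, 1, 0.5), rgied(n, 1, 0.5), sch)
  fit <- jgied_fit(d)
  cf <- coef(fit)
  Io <- jgied_observed_info(cf, d)$observed
  H <- jgied_hessian_info(cf, d)
  expect_equal(Io[1, 1], d$k1 / cf[["theta1"]]^2, tolerance = 1e-8)
  expect_equal(Io[1, 1], H[1, 1], tolerance = 1e-4)
  expect_equal(Io[2, 2], H[2, 2], tolerance = 1e-4)
  for (i in 1:3) for (j in 1:3) {
    expect_lt(abs(Io[i, j] - H[i, j]) / max(abs(H[i, j]), 1), 0.12)
  }
})

test_that("censored samples: theta1 block approximates k1/theta1^2 at scale", {
  set.seed(109)
  sch <- jpc_scheme(200, 250, 400, c(rep(0L, 199), 50L, rep(0L, 200)))
  d <- draw_valid_jpc(sch, 1, 1, 0.5)
  fit <- jgied_fit(d)
  cf <- coef(fit)
  Io <- jgied_observed_info(cf, d)$observed
  expect_lt(abs(Io[1, 1] - d$k1 / cf[["theta1"]]^2) / (d$k1 / cf[["theta1"]]^2),
            0.10)
})

test_that("doubling both lines roughly halves the variances", {
  sch1 <- jpc_scheme(20, 25, 25, "(0(9),20,0(15))")
  sch2 <- jpc_scheme(40, 50, 50, c(rep(0L, 18), 40L, rep(0L, 31)))
  set.seed(113)
  ratio <- replicate(30, {
    v1 <- diag(jgied_observed_info(c(theta1 = 1, theta2 = 1, lambda = 0.5),
                                   draw_valid_jpc(sch1, 1, 1, 0.5))$covariance)
    v2 <- diag(jgied_observed_info(c(theta1 = 1, theta2 = 1, lambda = 0.5),
                                   draw_valid_jpc(sch2, 1, 1, 0.5))$covariance)
    v2 / v1
  })
  expect_true(all(rowMeans(ratio) > 0.35 & rowMeans(ratio) < 0.65))
})
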