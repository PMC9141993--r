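test_that("complete-sample fitting is consistent", {
  set.seed(263)
  x <- rgied(5000, 2, 0.5)
  cf <- coef(gied_fit(x))
  expect_lt(abs(cf[["theta"]] - 2), 0.1)
  expect_lt(abs(cf[["lambda"]] - 0.5), 0.1)
  # Cox-Snell residuals of a correct fit are standard exponential
  r <- residuals(gied_fit(x[1:500]))
  expect_gt(suppressWarnings(stats::ks.test(r, "pexp"))$p.value, 0.001)
})

test_that("the classical K-S statistic matches stats::ks.test", {
  set.seed(269)
  for (r in 1:5) {
    x <- rgied(30, 1.5, 0.4)
    mine <- gied_ks(x, 1.5, 0.4, positions = "ecdf")
    ref <- suppressWarnings(stats::ks.test(x, function(q) pgied(q, 1.5, 0.4)))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    # asymptotic p against the exact small-sample p: close but not identical
    expect_lt(abs(mine$p.value - ref$p.value), 0.05)
  }
  # mean plotting positions give a smaller distance than the two-sided ecdf
  x <- rgied(30, 1.5, 0.4)
  expect_lte(gied_ks(x, 1.5, 0.4, "mean")$statistic,
             gied_ks(x, 1.5, 0.4, "ecdf")$statistic)
})

test_that("K-S p-values are roughly uniform under the null", {
  set.seed(271)
  pv <- replicate(300, gied_ks(rgied(30, 2, 0.5), 2, 0.5, "ecdf")$p.value)
  expect_lt(abs(mean(pv) - 0.5), 0.08)
  expect_gt(min(pv), 0); expect_lt(max(pv), 1 + 1e-12)
})

test_that("the likelihood-ratio test is calibrated at its extremes", {
  x <- jute10()
  # identical samples: the null is exactly attained
  same <- gied_lrt(x, x)
  expect_lt(same$statistic, 1e-6)
  expect_gt(same$p.value, 0.999)
  # strongly different lambdas: overwhelming rejection
  set.seed(277)
  rejections <- replicate(12, {
    gied_lrt(rgied(200, 1, 0.2), rgied(200, 1, 2))$p.value < 0.01
  })
  expect_gte(sum(rejections), 11)
})

test_that("the Monte Carlo driver tabulates coherent operating characteristics", {
  sch <- jpc_scheme(20, 25, 20, "(0(4),25,0(15))")
  set.seed(281)
  st <- jgied_mc_study(sch, 1, 1, 0.5, reps = 100)
  expect_s3_class(st, "jgied_mc_study")
  expect_true(all(is.finite(st$AE)) && all(is.finite(st$MSE)))
  expect_true(all(st$MSE >= 0))
  # bias-variance identity: MSE >= squared bias, always
  truth <- c(1, 1, 0.5)
  expect_true(all(st$MSE >= (st$AE - truth)^2 - 1e-12))
  # lambda is shared between the lines, so it is the best-estimated parameter
  expect_lt(st$MSE[st$parameter == "lambda"], st$MSE[st$parameter == "theta1"])
  # audit trail
  expect_equal(attr(st, "scheme"), "(0(4),25,0(15))")
  expect_equal(attr(st, "reps"), 100)
})

test_that("interval columns report lengths and coverage percentages", {
  sch <- small_scheme()
  set.seed(283)
  st <- jgied_mc_study(sch, 1, 1, 0.5, reps = 12, B = 40, M = 400)
  bs <- st[st$method == "bootstrap", ]
  cr <- st[st$method == "credible", ]
  expect_true(all(bs$AL > 0) && all(cr$AL > 0))
  expect_true(all(bs$CP >= 0 & bs$CP <= 100))
  expect_true(all(cr$CP >= 0 & cr$CP <= 100))
  expect_true(all(c("bayes_sel", "bayes_linex") %in% st$method))
})

test_that("study tables round-trip through CSV", {
  sch <- small_scheme()
  set.seed(293)
  st <- jgied_mc_study(sch, 1, 1, 0.5, reps = 5)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(st), f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$AE, st$AE, tolerance = 1e-12)
  expect_equal(back$MSE, st$MSE, tolerance = 1e-12)
  expect_equal(back$parameter, st$parameter)
  unlink(f)
})

test_that("the jute report reproduces its deterministic sections verbatim", {
  set.seed(307)
  rep1 <- jgied_real_data(schemes = "(0(14),30,0(15))", B = 30, M = 500)
  # complete-data block equals the direct fits
  f1 <- gied_fit(jute10())
  expect_equal(rep1$fits$theta[1], coef(f1)[["theta"]], tolerance = 1e-10)
  expect_equal(rep1$fits$lambda[1], coef(f1)[["lambda"]], tolerance = 1e-10)
  expect_equal(coef(rep1$joint), coef(rep1$lrt$null_fit))
  expect_match(rep1$meta$censored_data, "seed-dependent")
  # the whole report is a deterministic function of the seed
  set.seed(307)
  rep2 <- jgied_real_data(schemes = "(0(14),30,0(15))", B = 30, M = 500)
  expect_equal(rep1$censored[[1]]$bayes_sel, rep2$censored[[1]]$bayes_sel)
  expect_equal(rep1$censored[[1]]$boot_ci, rep2$censored[[1]]$boot_ci)
  expect_equal(coef(rep1$censored[[1]]$fit), coef(rep2$censored[[1]]$fit))
})
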