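test_that("log-normal MLE matches hand calculations and is equivariant", {
  # volumes e^-1, e^-3: mu = -2 and sigma = 1 with the divisor-n MLE
  fit <- fitLognormal(c(exp(-1), exp(-3), exp(-1), exp(-3)))
  expect_equal(fit@mu, -2)
  expect_equal(fit@sigma, 1)

  # degenerate sample: sigma 0, mu = log v
  fit0 <- fitLognormal(rep(5.87e-3, 10))
  expect_equal(fit0@mu, log(5.87e-3))
  expect_equal(fit0@sigma, 0)

  # scale equivariance: scaling by c shifts mu by log c, sigma unchanged
  set.seed(2)
  v <- rlnorm(200, -5.1375, 0.9173)
  f1 <- fitLognormal(v)
  f2 <- fitLognormal(1000 * v)
  expect_equal(f2@mu, f1@mu + log(1000))
  expect_equal(f2@sigma, f1@sigma)

  expect_error(fitLognormal(c(1, 2)), "at least 3")
  expect_error(fitLognormal(c(1, 0, 2)), "positive")
})

test_that("the MLE agrees with an independent fitting routine", {
  skip_if_not_installed("fitdistrplus")
  set.seed(7)
  v <- rlnorm(2000, -5.1375, 0.9173)
  fit <- fitLognormal(v)
  ref <- fitdistrplus::fitdist(v, "lnorm")
  # fitdistrplus uses the same MLE; numerical optimisation tolerance only
  expect_equal(fit@mu, unname(ref$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(fit@sigma, unname(ref$estimate["sdlog"]), tolerance = 1e-3)
  expect_equal(fit@logLik, as.numeric(ref$loglik), tolerance = 1e-6)
})

test_that("the fitted size distribution is consistent with the mean volume", {
  # exp(mu + sigma^2/2) at the reference parameters is within 2% of the
  # 8.80e-3 um^3 mean volume it summarises
  m <- exp(-5.1375 + 0.9173^2 / 2)
  expect_lt(abs(m - 8.80e-3) / 8.80e-3, 0.02)
})

test_that("concentration ratios divide percentages by volume fractions", {
  cr <- concentrationRatio(c(39.14, 42.70), c(38.50, 38.69),
                           c("dendrite", "nonsynaptic"))
  expect_equal(round(cr$ratio, 3), c(1.017, 1.104))
  expect_equal(concentrationRatio(25, 25)$ratio, 1)
  expect_error(concentrationRatio(10, 0), "positive")
})

test_that("chi-squared occupancy tests cover both forms", {
  # observed equal to expected: statistic 0, p 1
  r0 <- compartmentChiSquare(c(50, 30, 20), c(0.5, 0.3, 0.2))
  expect_equal(r0@statistic, 0)
  expect_equal(r0@pValue, 1)

  # hand calculation: (60,40) against (.5,.5) gives X2 = 4, df = 1
  r1 <- compartmentChiSquare(c(60, 40), c(0.5, 0.5))
  expect_equal(r1@statistic, 4)
  expect_equal(r1@df, 1)
  expect_equal(r1@pValue, pchisq(4, 1, lower.tail = FALSE))

  # the independence form conserves margins
  m <- rbind(c(30, 10, 5), c(20, 25, 10))
  ri <- compartmentChiSquare(m)
  expect_equal(rowSums(ri@expected), rowSums(m))
  expect_equal(colSums(ri@expected), colSums(m))
  expect_equal(ri@df, 2)

  # goodness of fit equals independence on a table of repeated rows
  obs <- c(60, 25, 15)
  gof <- compartmentChiSquare(obs, obs / sum(obs))
  ind <- compartmentChiSquare(rbind(obs, obs))
  expect_equal(gof@statistic, 0)
  expect_equal(ind@statistic, 0)

  expect_error(compartmentChiSquare(c(10, 10), c(1, 0)), "zero")
  expect_warning(compartmentChiSquare(c(10, 10), c(0.6, 0.6)),
                 "renormalizing")
})

test_that("group comparisons reproduce an independent rank-test oracle", {
  a <- c(1.2, 3.4, 2.2, 4.1, 2.8)
  b <- c(5.1, 6.0, 4.9, 7.2, 6.5)
  c3 <- c(2.9, 3.1, 4.0, 3.6, 5.0)
  vals <- c(a, b, c3)
  grp <- rep(c("a", "b", "c"), each = 5)

  res <- groupCompare(vals, grp)
  expect_identical(res$method, "kruskal_wallis")
  # frozen oracle values (independent implementation of the same formulas)
  expect_equal(res$statistic, 9.62, tolerance = 1e-10)
  expect_equal(res$p.value, 0.008147859697680, tolerance = 1e-10)
  ph <- res$posthoc
  expect_equal(ph$z, c(-3.040559159102155, -0.989949493661166,
                       2.050609665440988), tolerance = 1e-10)
  expect_equal(ph$p, c(0.002361392962675, 0.322198806162582,
                       0.040304974362541), tolerance = 1e-10)
  expect_equal(ph$p_adjusted, c(0.007084178888024, 0.322198806162582,
                                0.080609948725082), tolerance = 1e-10)
  # adjusted p never smaller than unadjusted
  expect_true(all(ph$p_adjusted >= ph$p - 1e-15))

  mw <- groupCompare(c(a, b), rep(c("a", "b"), each = 5))
  expect_identical(mw$method, "mann_whitney")
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 0.009023438818080, tolerance = 1e-10)

  expect_error(groupCompare(a, rep("a", 5), design = "k_group"),
               "at least 2")
  expect_error(groupCompare(vals, grp, design = "two_group"), "exactly 2")
})

test_that("layer/compartment summaries have the reported table shape", {
  cat6 <- generateCatalog(
    catalogSpec(nStacks = 6L, layers = c("I", "II", "III", "IV", "V", "VI")),
    csrProcess(0.21), seed = 23)
  tabP <- layerCompartmentSummary(cat6, "percent")
  expect_identical(tabP$layer, c("I", "II", "III", "IV", "V", "VI", "I-VI"))
  expect_identical(ncol(tabP), 9L)  # layer + 4 compartments x (mean, sem)
  # percentages over compartments sum to 100 within rounding
  pooled <- tabP[tabP$layer == "I-VI", grep("_mean", names(tabP))]
  expect_lt(abs(sum(pooled) - 100), 0.1)

  tabV <- layerCompartmentSummary(cat6, "volume")
  expect_identical(nrow(tabV), 7L)
})
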