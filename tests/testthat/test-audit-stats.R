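test_that("detection probability follows 1 - (1-p)^n and is monotone", {
  expect_equal(detectionProbability(0, 1000), 0)
  expect_equal(detectionProbability(1, 1), 1)
  expect_equal(detectionProbability(0.01, 300), 1 - 0.99^300)
  expect_gte(detectionProbability(0.01, 300), 0.95)
  # strictly increasing in n and p on (0,1)
  p <- seq(0.001, 0.2, length.out = 25)
  expect_true(all(diff(detectionProbability(p, 50)) > 0))
  expect_true(all(diff(detectionProbability(0.01, c(10, 50, 100, 500))) > 0))
  expect_error(detectionProbability(1.2, 10), "0, 1")
})

test_that("required sample size is the minimal n meeting the target", {
  expect_identical(requiredSampleSize(0.95, 0.01), 299L)
  expect_identical(requiredSampleSize(0.95, 0.01, "next-hundred"), 300L)
  expect_identical(requiredSampleSize(0.5, 0.5), 1L)
  # minimality: n works, n-1 does not, over a parameter grid
  for (p in c(0.005, 0.01, 0.03, 0.2)) {
    for (tp in c(0.8, 0.9, 0.95, 0.99)) {
      n <- requiredSampleSize(tp, p)
      expect_gte(detectionProbability(p, n), tp)
      if (n > 1) expect_lt(detectionProbability(p, n - 1), tp)
    }
  }
  expect_error(requiredSampleSize(0.95, 0), "0, 1")
})

test_that("exact interval matches the Clopper-Pearson construction", {
  ci <- exactBinomialCI(0, 300)
  expect_identical(unname(ci["low"]), 0)
  expect_equal(round(unname(ci["high"]), 3), 0.012)
  expect_equal(round(unname(exactBinomialCI(1, 300)["high"]), 3), 0.018)
  # independent oracle: stats::binom.test uses the same exact construction
  for (k in c(0, 1, 7, 150, 300)) {
    want <- stats::binom.test(k, 300)$conf.int
    got <- exactBinomialCI(k, 300)
    expect_equal(unname(got["low"]), want[1], tolerance = 1e-10)
    expect_equal(unname(got["high"]), want[2], tolerance = 1e-10)
  }
  # k = n mirrors k = 0 under k -> n-k
  ci10 <- exactBinomialCI(10, 10)
  ci0 <- exactBinomialCI(0, 10)
  expect_identical(unname(ci10["high"]), 1)
  expect_equal(unname(ci10["low"]), 1 - unname(ci0["high"]))
  expect_error(exactBinomialCI(5, 4), "k <= n")
})

test_that("posterior count percentiles agree with the closed-form k=0 oracle", {
  obs <- auditObservation("Arthropoda", 300, 0, 2008162)
  got <- posteriorCountPercentiles(obs, draws = 200000, seed = 77)
  # for k = 0 the posterior is Beta(1, n+1) with quantile 1-(1-q)^(1/(n+1))
  closed <- function(q) (1 - (1 - q)^(1 / 301)) * 2008162
  # Monte-Carlo error bound: 3 standard errors of the quantile estimator
  se <- function(q) {
    f <- 301 / 2008162 * (1 - (closed(q) / 2008162))^300
    sqrt(q * (1 - q) / 200000) / f
  }
  for (q in c(0.05, 0.5, 0.95)) {
    expect_lt(abs(got[[paste0("p", 100 * q)]] - closed(q)), 3 * se(q) + 1)
  }
  # percentiles are monotone and reproducible under the same seed
  expect_true(all(diff(got) >= 0))
  expect_identical(posteriorCountPercentiles(obs, seed = 5),
                   posteriorCountPercentiles(obs, seed = 5))
  expect_error(posteriorCountPercentiles(obs, draws = 10), "1000")
})

test_that("predictive counts match the beta-binomial mean and edge cases", {
  obs <- auditObservation("Mollusca", 300, 1, 109502)
  pc <- predictiveSampleCounts(obs, sampleSizes = c(0, 300, 10000),
                               draws = 10000, seed = 13)
  expect_true(all(pc["0", ] == 0L))
  expect_true(all(diff(t(pc)[, 3]) >= 0))
  # marginal mean ~ s * (k+1)/(n+2) within 3 standard errors
  set.seed(14)
  s <- 10000
  p <- rbeta(50000, 2, 300)
  x <- rbinom(50000, s, p)
  muWant <- s * 2 / 302
  expect_lt(abs(mean(x) - muWant), 3 * stats::sd(x) / sqrt(50000))
  expect_identical(predictiveSampleCounts(obs, seed = 9),
                   predictiveSampleCounts(obs, seed = 9))
})

test_that("census rates reproduce per-class and combined percentages", {
  r <- censusRates(c(bacterial = 2, fungal = 1, other_metazoan = 22), 363)
  expect_equal(unname(r$perClass["other_metazoan"]), 6.06)
  expect_equal(round(r$combined, 1), 6.9)
  expect_equal(unname(round(r$perClass["bacterial"], 1)), 0.6)
  expect_equal(unname(round(r$perClass["fungal"], 1)), 0.3)
  r0 <- censusRates(integer(0), 100)
  expect_identical(r0$combined, 0)
  expect_error(censusRates(c(a = 1), 0), "positive")
  expect_error(censusRates(c(a = 80, b = 30), 100), "exceeds")
})

test_that("auditEstimate bundles all pieces reproducibly", {
  obs <- auditObservation("Mollusca", 300, 1, 109502)
  est <- auditEstimate(obs, seed = 42)
  expect_s4_class(est, "AuditEstimate")
  expect_equal(est@pointRatio, 1 / 300)
  expect_true(est@ciLow <= est@pointRatio && est@pointRatio <= est@ciHigh)
  est2 <- auditEstimate(obs, seed = 42)
  expect_identical(est@countPercentiles, est2@countPercentiles)
  expect_identical(est@predictiveCounts, est2@predictiveCounts)
  lst <- auditEstimateAsList(est)
  expect_identical(lst$k, 1L)
  expect_identical(lst$count_percentiles$p50, unname(est@countPercentiles["p50"]))
  expect_error(auditObservation("x", 10, 11, 100), "k must")
  expect_error(auditObservation("x", 10, 2, 5), "nTotal")
})
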