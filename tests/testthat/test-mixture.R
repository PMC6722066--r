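test_that("single-component fit is the closed-form exponential MLE", {
  set.seed(71)
  x <- 1.5 + rexp(2000, 1 / 9)
  m <- fitExpMixture(x, 1)
  expect_equal(m@rates, 1 / mean(x - 1.5))
  expect_equal(m@weights, 1)
  expect_equal(m@bic, -2 * m@logLik + log(2000))
})

test_that("EM log-likelihood never decreases", {
  set.seed(72)
  for (r in 1:4) {
    x <- c(1.5 + rexp(400, 1 / 15), 1.5 + rexp(150, 1.2))
    m <- fitExpMixture(x, sample(2:3, 1), traceLik = TRUE, seed = r)
    tr <- attr(m, "logLikTrace")
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  }
})

test_that("fitting is invariant to shifting the lengths", {
  set.seed(73)
  x <- c(3 + rexp(500, 1 / 12), 3 + rexp(200, 1))
  m1 <- fitExpMixture(x, 2, shift = 3, seed = 9)
  m2 <- fitExpMixture(x - 3, 2, shift = 0, seed = 9)
  expect_equal(m1@weights, m2@weights, tolerance = 1e-8)
  expect_equal(m1@rates, m2@rates, tolerance = 1e-8)
  expect_equal(m1@logLik, m2@logLik, tolerance = 1e-8)
})

test_that("components are ordered by decreasing mean and sum to one", {
  set.seed(74)
  x <- c(1.5 + rexp(800, 1 / 14), 1.5 + rexp(300, 1.4))
  m <- fitExpMixture(x, 2, seed = 10)
  expect_true(all(diff(m@rates) >= 0))
  expect_equal(sum(m@weights), 1)
})

test_that("an 84:16 mixture with means 15.7 and 0.72 Mb is recovered", {
  set.seed(75)
  truth <- expMixtureModel(c(0.84, 0.16), c(1 / 15.7, 1 / 0.72))
  x <- rExpMixture(4196, truth)
  m <- fitExpMixture(x, 2, seed = 11)
  expect_lt(abs(m@weights[1] - 0.84), 0.05)
  expect_lt(abs(1 / m@rates[1] - 15.7) / 15.7, 0.15)
  expect_lt(abs(1 / m@rates[2] - 0.72) / 0.72, 0.15)
})

test_that("degenerate equal lengths are handled as specified", {
  x <- rep(4.5, 50)
  m1 <- fitExpMixture(x, 1)
  expect_equal(m1@rates, 1 / 3)  # 1 / (value - shift)
  m2 <- fitExpMixture(x, 2)
  expect_true("nonidentifiable" %in% m2@flags)
})

test_that("lengths at or below the shift are rejected", {
  expect_error(fitExpMixture(c(1.4, 2, 3), 1), "exceed the shift")
  expect_error(piLogLik(c(2, 3), 1.2, referenceDensities()), "pi")
})

test_that("BIC selects the true component count", {
  set.seed(76)
  x1 <- 1.5 + rexp(10000, 1 / 10)
  s1 <- selectExpMixtureK(x1, kMax = 3, seed = 12)
  expect_equal(s1$K, 1)
  truth <- expMixtureModel(c(0.6, 0.4), c(1 / 20, 2))
  x2 <- rExpMixture(10000, truth)
  s2 <- selectExpMixtureK(x2, kMax = 3, seed = 13)
  expect_equal(s2$K, 2)
  expect_equal(s2$bic[2], s2$models[[2]]@bic)
})

test_that("density integrates to one and simulation matches it", {
  m <- expMixtureModel(c(0.7, 0.3), c(0.06, 1.2))
  expect_equal(stats::integrate(dExpMixture, 1.5, Inf, model = m,
                                rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  expect_equal(dExpMixture(1.4, m), 0)
  set.seed(77)
  x <- rExpMixture(40000, m)
  expect_equal(mean(x), 1.5 + sum(m@weights / m@rates), tolerance = 0.05)
})

test_that("JSON serialization round-trips a fitted model", {
  set.seed(78)
  x <- 1.5 + rexp(500, 1 / 7)
  m <- fitExpMixture(x, 2, seed = 14)
  f <- withr::local_tempfile(fileext = ".json")
  writeExpMixture(m, f)
  m2 <- readExpMixture(f)
  expect_equal(m2@weights, m@weights)
  expect_equal(m2@rates, m@rates)
  expect_equal(m2@logLik, m@logLik)
})

test_that("the gamma comparison fits worse than a well-specified 2-mixture", {
  set.seed(79)
  truth <- expMixtureModel(c(0.8, 0.2), c(0.06, 1.4))
  x <- rExpMixture(5000, truth)
  m <- fitExpMixture(x, 2, seed = 15)
  g <- gammaComparisonBIC(x)
  expect_gt(g$bic, m@bic)
})
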