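test_that("noise-free linear fits recover the planted slope exactly", {
  set.seed(101)
  f <- c(runif(300, 0, 0.02), runif(40, 0.1, 0.3))
  cov <- data.frame(a = rnorm(340), b = rnorm(340))
  y <- 2 + 0.5 * cov$a - 0.3 * cov$b - 3.2 * f
  fit <- suppressWarnings(fitInbreedingLm(y, f, cov))
  expect_equal(fit$effect, -3.2, tolerance = 1e-10)
})

test_that("planted depression slopes are recovered within sampling error", {
  set.seed(102)
  prof <- data.frame(fROH = c(abs(rnorm(20000, 0.003, 0.002)),
                              rnorm(60, 0.17, 0.05)))
  ph <- simulatePhenotypes(prof, traitSlopes = c(T1 = -3.88, T2 = 0),
                           seed = 103)
  cov <- ph[, c("age", "tdi", "centre")]
  f1 <- fitInbreedingLm(ph$T1, ph$fROH, cov)
  expect_lt(abs(f1$effect + 3.88), 2 * f1$se)
  ## null trait: no spurious depression
  f2 <- fitInbreedingLm(ph$T2, ph$fROH, cov)
  expect_lt(abs(f2$effect), 3 * f2$se)
})

test_that("collinear covariates are reported by name", {
  set.seed(104)
  cov <- data.frame(a = rnorm(100))
  cov$b <- 2 * cov$a
  expect_error(fitInbreedingLm(rnorm(100), rnorm(100), cov),
               "collinear.*b")
})

test_that("quasi-Poisson SEs match plain Poisson when dispersion is one", {
  set.seed(105)
  prof <- data.frame(fROH = runif(20000, 0, 0.3))
  ph <- simulatePhenotypes(prof, traitSlopes = c(T = -1),
                           countB = 1.0, countTheta = Inf, seed = 106)
  qp <- fitInbreedingQuasiPoisson(ph$count, ph$fROH,
                                  ph[, c("age", "tdi")])
  pois <- glm(ph$count ~ ph$fROH + ph$age + ph$tdi, family = poisson)
  seP <- summary(pois)$coefficients[2, 2]
  expect_lt(abs(qp$se - seP) / seP, 0.05)
  expect_lt(abs(qp$dispersion - 1), 0.05)
  expect_lt(abs(qp$inbreedingLoad - 1.0), 3 * qp$se)
})

test_that("overdispersed counts inflate the dispersion and keep B unbiased", {
  set.seed(107)
  prof <- data.frame(fROH = runif(40000, 0, 0.25))
  ph <- simulatePhenotypes(prof, traitSlopes = c(T = 0), countB = 1.46,
                           countTheta = 5, seed = 108)
  qp <- fitInbreedingQuasiPoisson(ph$count, ph$fROH, ph[, c("age", "tdi")])
  expect_gt(qp$dispersion, 1.1)
  expect_lt(abs(qp$inbreedingLoad - 1.46), 3 * qp$se)
  ## load / relative-risk arithmetic
  expect_equal(-log(qp$RR), qp$inbreedingLoad)
  expect_equal(-log(0.23), 1.47, tolerance = 0.005)
  expect_error(fitInbreedingQuasiPoisson(rep(0L, 50), rnorm(50)),
               "degenerate")
  expect_error(fitInbreedingQuasiPoisson(c(-1, 2), rnorm(2)),
               "non-negative")
})

test_that("extrapolated effects divide by the inbreeding contrast", {
  expect_equal(extrapolateEffect(-0.656, 0.172, 0.003), -3.88,
               tolerance = 0.002)
  expect_equal(extrapolateEffect(-0.417, 0.172, 0.003), -2.46,
               tolerance = 0.01)
  expect_equal(extrapolateEffect(0, 0.2, 0.01), 0)
  expect_error(extrapolateEffect(-1, 0.1, 0.1), "exceed")
})

test_that("linearity test is exact under equality and calibrated under the null", {
  z0 <- linearityTest(-0.5, 0.1, -2.94, 0.4, 0.17)
  expect_equal(z0$z, (-0.5 - -2.94 * 0.17) / sqrt(0.1^2 + (0.17 * 0.4)^2))
  same <- linearityTest(-0.68, 0.1, -4, 0.3, 0.17)
  expect_equal(same$predicted, -0.68)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("pre-adjustment residualizes, normalizes and excludes outliers", {
  set.seed(109)
  cov <- data.frame(a = rnorm(3000))
  y <- 3 * cov$a + rnorm(3000)
  z <- preAdjustTrait(y, cov)
  expect_lt(abs(mean(z, na.rm = TRUE)), 0.05)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 0.05)
  expect_true(all(abs(z) <= 4, na.rm = TRUE))
  ## the covariate signal is gone
  expect_lt(abs(cor(z, cov$a, use = "complete.obs")), 0.05)
})

test_that("a null inbreeding effect produces no case-control difference", {
  set.seed(110)
  prof <- data.frame(fROH = c(abs(rnorm(5000, 0.003, 0.002)),
                              rnorm(50, 0.17, 0.05)))
  ph <- simulatePhenotypes(prof, traitSlopes = c(T = 0), seed = 111)
  ei <- ph$fROH > 0.1
  fit <- fitInbreedingLm(ph$T, as.numeric(ei), ph[, c("age", "tdi")])
  expect_lt(abs(fit$effect), 3 * fit$se)
})
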