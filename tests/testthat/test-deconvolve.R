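test_that("pi boundaries reduce to pure reference log-likelihoods", {
  refs <- referenceDensities()
  set.seed(81)
  x <- rExpMixture(200, refs$fPO)
  expect_equal(piLogLik(x, 1, refs), sum(dExpMixture(x, refs$fPO, log = TRUE)))
  expect_equal(piLogLik(x, 0, refs), sum(dExpMixture(x, refs$fFS, log = TRUE)))
})

test_that("segments where the densities agree contribute independently of pi", {
  refs <- referenceDensities()
  ## solve f_PO(x) = f_FS(x) numerically, then check invariance
  xeq <- stats::uniroot(function(x) dExpMixture(x, refs$fPO) -
                          dExpMixture(x, refs$fFS), c(2, 30),
                        tol = 1e-12)$root
  lls <- vapply(c(0, 0.3, 0.7, 1), function(p) piLogLik(xeq, p, refs), 0)
  expect_lt(diff(range(lls)), 1e-8)
})

test_that("identical reference densities are rejected as non-identifiable", {
  refs <- referenceDensities()
  refs$fFS <- refs$fPO
  expect_error(estimatePi(c(2, 3, 4), refs), "identifiable")
})

test_that("optimizer maximum matches a fine grid search", {
  refs <- referenceDensities()
  set.seed(82)
  x <- c(rExpMixture(1200, refs$fPO), rExpMixture(1000, refs$fFS))
  est <- estimatePi(x, refs, mcDraws = 1e4, seed = 1)
  grid <- seq(0, 1, by = 1e-3)
  ll <- vapply(grid, function(p) piLogLik(x, p, refs), 0)
  expect_lt(abs(est$pi - grid[which.max(ll)]), 1e-3)
  ## numerical concavity of the profile likelihood
  expect_true(all(diff(ll, differences = 2) < 1e-6))
})

test_that("pure PO segments drive pi to the boundary", {
  refs <- referenceDensities()
  set.seed(83)
  x <- rExpMixture(10000, refs$fPO)
  est <- estimatePi(x, refs, mcDraws = 1e4, seed = 2)
  expect_gt(est$pi, 0.93)
})

test_that("the asymptotic SE scales as 1/sqrt(n)", {
  refs <- referenceDensities()
  set.seed(84)
  x1 <- c(rExpMixture(1122, refs$fPO), rExpMixture(1122, refs$fFS))
  x4 <- c(rExpMixture(4488, refs$fPO), rExpMixture(4488, refs$fFS))
  e1 <- estimatePi(x1, refs, mcDraws = 4e4, seed = 3)
  e4 <- estimatePi(x4, refs, mcDraws = 4e4, seed = 4)
  expect_equal(e1$se / e4$se, 2, tolerance = 0.2)
  expect_true(e1$lower >= 0 && e1$upper <= 1)
})

test_that("group assignment follows the per-individual likelihood ratio", {
  refs <- referenceDensities()
  set.seed(85)
  ## ~50 autosomal segments per case, as observed for MT1 offspring
  po <- replicate(150, rExpMixture(50, refs$fPO), simplify = FALSE)
  fs <- replicate(150, rExpMixture(50, refs$fFS), simplify = FALSE)
  gpo <- assignMatingGroups(po, refs)
  gfs <- assignMatingGroups(fs, refs)
  expect_gt(mean(gpo == "Group2"), 0.6)   # PO-like -> Group2
  expect_gt(mean(gfs == "Group1"), 0.6)
  expect_gt(mean(c(gpo == "Group2", gfs == "Group1")), 0.65)
  ## exactly equal likelihoods under both references are a tie
  tiedRefs <- refs
  tiedRefs$fFS <- tiedRefs$fPO
  expect_true(is.na(assignMatingGroups(list(c(3, 7)), tiedRefs)))
  expect_error(assignMatingGroups(list(numeric(0)), refs), "at least one")
})

test_that("X-chromosome F matches PO/FS expectations, marginally and within
          likelihood-assigned groups", {
  set.seed(86)
  poX <- simulateXFroh("PO", 400, seed = 91)
  fsX <- simulateXFroh("FS", 400, seed = 92)
  expect_lt(abs(mean(poX) - 0.5), 4 * sd(poX) / sqrt(400))
  expect_lt(abs(mean(fsX) - 0.25), 4 * sd(fsX) / sqrt(400))

  ## females of known pedigree: autosomal HBD lengths drive the grouping,
  ## the groups' X inbreeding should then separate towards 0.5 vs 0.25
  map <- makeGeneticMap(seed = 87)
  po <- simulateHbdCohort("PO", 100, map, perIndividual = TRUE, seed = 88)
  fs <- simulateHbdCohort("FS", 100, map, perIndividual = TRUE, seed = 89)
  refs <- fitReferenceDensities(po$lengthsMb[po$lengthsMb > 1.5],
                                fs$lengthsMb[fs$lengthsMb > 1.5],
                                nRestarts = 2, seed = 90)
  lens <- c(lapply(po$perIndividual, function(x) x[x > 1.5]),
            lapply(fs$perIndividual, function(x) x[x > 1.5]))
  grp <- assignMatingGroups(lens, refs)
  truePo <- rep(c(TRUE, FALSE), each = 100)
  expect_gt(mean(grp[truePo] == "Group2", na.rm = TRUE), 0.6)
  xval <- c(poX[1:100], fsX[1:100])
  m2 <- mean(xval[grp == "Group2"], na.rm = TRUE)
  m1 <- mean(xval[grp == "Group1"], na.rm = TRUE)
  expect_gt(m2, m1)            # PO-like group has higher X inbreeding
  expect_lt(abs(m2 - 0.5), 0.12)
  expect_lt(abs(m1 - 0.25), 0.12)
})
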