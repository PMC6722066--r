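test_that("a 2 cM map interval receives a breakpoint with probability 0.02", {
  map <- makeGeneticMap(nChrom = 1, physicalLengthsBp = 1e6,
                        geneticLengthsCm = 2, heterogeneity = 0)
  mi <- ROHmix:::.mapIntervals(map)
  expect_equal(mi$pB, 0.02)
})

test_that("a near-zero genetic length chromosome transmits intact haplotypes", {
  map <- makeGeneticMap(nChrom = 1, physicalLengthsBp = 5e7,
                        geneticLengthsCm = 1e-9, heterogeneity = 0)
  panel <- makeSnpPanel(map, densityPerMb = 10, seed = 31)
  fp <- makeFounders(panel, 2, seed = 32)
  set.seed(33)
  og <- simulateMating("UN", fp, withGenotypes = FALSE)
  ## each inherited haplotype is one founder haplotype, unrecombined
  expect_equal(length(og@tiling1$l), 1)
  expect_equal(length(og@tiling2$l), 1)
})

test_that("breakpoint counts match the sum of per-interval Bernoulli means", {
  map <- smallMap(seed = 34)
  mi <- ROHmix:::.mapIntervals(map)
  tA <- ROHmix:::.founderTiling(mi, 1L)
  tB <- ROHmix:::.founderTiling(mi, 2L)
  set.seed(35)
  nrep <- 400
  ## internal boundaries = visible breakpoints plus the always-kept
  ## chromosome-1/2 junction, so subtract 2 ends in total
  nb <- replicate(nrep, length(ROHmix:::.meiose(tA, tB, mi)$e) - 2)
  expected <- sum(mi$pB)
  expect_lt(abs(mean(nb) - expected), 4 * sqrt(expected / nrep))
})

test_that("gamete tilings cover the genome exactly once", {
  mi <- ROHmix:::.mapIntervals(smallMap())
  set.seed(36)
  for (r in 1:20) {
    g <- ROHmix:::.meiose(ROHmix:::.founderTiling(mi, 1L),
                          ROHmix:::.founderTiling(mi, 2L), mi)
    expect_false(is.unsorted(g$e, strictly = TRUE))
    expect_equal(g$e[length(g$e)], mi$totalBp)
    expect_true(all(g$l %in% c(1L, 2L)))
  }
})

test_that("HBD fractions match pedigree inbreeding coefficients", {
  map <- smallMap(seed = 37)
  for (ty in c("PO", "FS", "HS", "FC")) {
    res <- simulateHbdCohort(ty, 600, map, collectLengths = FALSE,
                             seed = 38 + match(ty, c("PO", "FS", "HS", "FC")))
    fhat <- mean(res$stats$hbdFraction)
    se <- sd(res$stats$hbdFraction) / sqrt(600)
    expect_lt(abs(fhat - expectedF(ty)), 4 * se)
  }
})

test_that("UN matings of background-off founders yield no HBD", {
  map <- smallMap()
  res <- simulateHbdCohort("UN", 50, map, seed = 42)
  expect_true(all(res$stats$nSegments == 0))
})

test_that("mating metadata follows the pedigree definitions", {
  expect_equal(matingClass(c("PO", "FS")), c("MT1", "MT1"))
  expect_equal(matingClass(c("HS", "AV", "GP", "DC")), rep("MT2", 4))
  expect_equal(matingClass("FC"), "MT3")
  expect_equal(expectedF(c("PO", "HS", "FC", "UN")),
               c(0.25, 0.125, 0.0625, 0))
  expect_error(simulateMating("XX", smallFounders()), "arg")
})

test_that("trueHbdSegments returns disjoint per-chromosome HBD ranges", {
  fp <- smallFounders()
  set.seed(43)
  og <- simulateMating("FS", fp, withGenotypes = FALSE)
  seg <- trueHbdSegments(og)
  if (length(seg) > 1) {
    expect_equal(length(GenomicRanges::reduce(seg)), length(seg))
  }
  expect_true(all(S4Vectors::mcols(seg)$kind == "HBD"))
  expect_equal(sum(S4Vectors::mcols(seg)$lengthMb) /
                 physicalLengthMb(og@map), trueHbdFraction(og),
               tolerance = 1e-6)
})

test_that("genotypes are consistent with founder haplotypes before errors", {
  fp <- smallFounders()
  set.seed(44)
  og <- simulateMating("FS", fp, withGenotypes = TRUE, errorRate = NULL)
  expect_true(all(og@genotypes %in% 0:2))
  ## inside an HBD segment the genotype must be homozygous
  seg <- trueHbdSegments(og)
  if (length(seg)) {
    p <- fp@panel
    s1 <- seg[1]
    sel <- p@chromIdx == match(as.character(GenomicRanges::seqnames(s1)),
                               p@map@chromNames) &
      p@posBp >= GenomicRanges::start(s1) & p@posBp <= GenomicRanges::end(s1)
    expect_true(all(og@genotypes[sel] != 1L))
  }
})

test_that("genotyping error injection has the stated Poisson mean and support", {
  fp <- smallFounders()
  panel <- fp@panel
  set.seed(45)
  og <- simulateMating("UN", fp, withGenotypes = TRUE, errorRate = NULL)
  g0 <- og@genotypes
  expect_identical(injectGenotypingErrors(g0, panel, rate = 0), g0)
  nrep <- 60; rate <- 0.002
  nerr <- replicate(nrep, sum(injectGenotypingErrors(g0, panel,
                                                     rate = rate) != g0))
  lambda <- rate * nSnps(panel)
  expect_lt(abs(mean(nerr) - lambda), 4 * sqrt(lambda / nrep))
  g1 <- injectGenotypingErrors(g0, panel, rate = 0.01)
  expect_true(all(g1 %in% 0:2))
  expect_error(injectGenotypingErrors(g0, panel, rate = -1), ">= 0")
})

test_that("sampleGamete reports origin segments on chromosome scale", {
  fp <- smallFounders()
  set.seed(46)
  og <- simulateMating("PO", fp, withGenotypes = FALSE)
  gam <- sampleGamete(og, seed = 47)
  expect_true(all(gam$end_bp > gam$start_bp))
  expect_setequal(unique(gam$chrom), chromNames(og@map))
})
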