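test_that("caller matches the exhaustive window-scan oracle on toy inputs", {
  set.seed(51)
  for (rep in 1:6) {
    n <- 2500
    panel <- toyPanel(n, spacingBp = sample(c(8000, 12000), 1))
    ## mosaic genotype: stretches of homozygosity with sprinkled hets,
    ## missing calls, and noisy heterozygous regions
    g <- integer(n)
    at <- 1
    while (at < n) {
      len <- sample(60:600, 1)
      to <- min(n, at + len - 1)
      if (runif(1) < 0.5) {
        g[at:to] <- sample(c(0L, 2L), to - at + 1, replace = TRUE)
        hets <- which(rbinom(to - at + 1, 1, 0.01) == 1)
        g[at - 1 + hets] <- 1L
      } else {
        g[at:to] <- sample(0:2, to - at + 1, replace = TRUE,
                           prob = c(0.3, 0.4, 0.3))
      }
      at <- to + 1
    }
    g[sample.int(n, 25)] <- NA
    for (minKb in c(1500, 2000)) {
      p <- rohParams(minKb = minKb)
      got <- rohIndexTable(callROH(g, panel, p), panel@posBp)
      want <- bruteForceRoh(g, panel@posBp, p)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("fully homozygous chromosome yields one ROH spanning all SNPs", {
  panel <- toyPanel(2000, spacingBp = 10000)  # 2000 SNPs over 20 Mb
  g <- rep(2L, 2000)
  seg <- callROH(g, panel)
  expect_equal(length(seg), 1)
  expect_equal(GenomicRanges::start(seg), panel@posBp[1])
  expect_equal(GenomicRanges::end(seg), panel@posBp[2000])
  expect_equal(S4Vectors::mcols(seg)$nSnps, 2000L)
})

test_that("all-heterozygous input and sub-threshold tracts yield nothing", {
  panel <- toyPanel(2000, spacingBp = 10000)
  expect_equal(length(callROH(rep(1L, 2000), panel)), 0)
  ## planted 1.4 Mb homozygous tract: below the 1.5 Mb minimum
  g <- rep(1L, 2000)
  g[1000:1139] <- 0L  # 140 SNPs x 10 kb = 1.39 Mb
  expect_equal(length(callROH(g, panel)), 0)
})

test_that("raising the minimum length never increases N_ROH or F_ROH", {
  fp <- smallFounders()
  set.seed(52)
  for (r in 1:4) {
    og <- simulateMating("FS", fp, errorRate = 4.5e-4)
    prev <- NULL
    for (minKb in c(1500, 2000, 5000)) {
      seg <- callROH(og@genotypes, fp@panel, rohParams(minKb = minKb))
      cur <- c(length(seg), sum(S4Vectors::mcols(seg)$lengthMb))
      if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
      prev <- cur
    }
  }
})

test_that("F_ROH is segment length over the autosome denominator", {
  gr <- GenomicRanges::GRanges(c("1", "2"),
        IRanges::IRanges(start = c(1, 1), width = c(2e8, 8.81e7)))
  S4Vectors::mcols(gr)$lengthMb <- c(200, 88.1)
  expect_equal(fROH(gr), 0.1)
  expect_equal(fROH(GenomicRanges::GRanges()), 0)
  ov <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 100), c(1e6, 2e6)))
  expect_error(fROH(ov), "disjoint")
})

test_that("F_UNI matches its plug-in values and is centred under HWE", {
  expect_equal(fUNI(1L, 0.5), -1)
  expect_equal(fUNI(0L, 0.5), 1)
  expect_equal(fUNI(2L, 0.5), 1)
  set.seed(53)
  p <- runif(1e5, 0.05, 0.95)
  g <- rbinom(1e5, 2, p)
  se <- 1 / sqrt(1e5)  # per-SNP contribution has unit-scale variance
  expect_lt(abs(fUNI(g, p)), 4 * se)
  expect_error(fUNI(c(0L, 1L), c(0, 0.5)), "inside")
})

test_that("F_ROH-X uses the X denominator and rejects males", {
  gr <- GenomicRanges::GRanges("X", IRanges::IRanges(1, 7.75e7))
  S4Vectors::mcols(gr)$lengthMb <- 77.5
  expect_equal(fROHX(gr), 0.5)
  expect_equal(fROHX(GenomicRanges::GRanges()), 0)
  expect_error(fROHX(gr, sex = "male"), "female")
})

test_that("inbreeding profile summarizes the called segments", {
  fp <- smallFounders()
  set.seed(54)
  og <- simulateMating("PO", fp, errorRate = NULL)
  pr <- inbreedingProfile(og@genotypes, fp@panel, denominatorMb = 110,
                          id = "po1")
  seg <- attr(pr, "segments")
  expect_equal(pr$nROH, length(seg))
  expect_equal(pr$fROH, sum(S4Vectors::mcols(seg)$lengthMb) / 110)
  expect_gt(pr$fROH, 0.05)
  expect_gt(pr$fUNI, 0.05)
})

test_that(".hom-style and genotype tables round-trip through files", {
  fp <- smallFounders()
  set.seed(55)
  og <- simulateMating("FS", fp, errorRate = NULL)
  seg <- callROH(og@genotypes, fp@panel)
  hom <- homTable(seg, iid = "fs1")
  f <- withr::local_tempfile(fileext = ".hom")
  writeHom(hom, f)
  expect_equal(readHom(f), hom, tolerance = 1e-12)

  gf <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(cbind(a = og@genotypes), fp@panel, gf)
  back <- readGenotypes(gf)
  expect_equal(unname(back$geno[, 1]), og@genotypes)
  expect_equal(back$pos_bp, fp@panel@posBp)
})
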