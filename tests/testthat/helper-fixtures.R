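## Shared small-genome fixtures (built once per test run) and an
## exhaustive reference implementation of the ROH scan.

smallMap <- function(het = 1, seed = 101) {
  makeGeneticMap(nChrom = 2, physicalLengthsBp = c(6e7, 5e7),
                 geneticLengthsCm = c(80, 70), heterogeneity = het,
                 seed = seed)
}

.fixEnv <- new.env()

smallPanel <- function() {
  if (is.null(.fixEnv$panel))
    .fixEnv$panel <- makeSnpPanel(smallMap(), densityPerMb = 60, seed = 102)
  .fixEnv$panel
}

smallFounders <- function() {
  if (is.null(.fixEnv$founders))
    .fixEnv$founders <- makeFounders(smallPanel(), 30, seed = 103)
  .fixEnv$founders
}

## Exhaustive ROH reference: every window enumerated, every run constraint
## checked directly with explicit loops. Independent of the vectorized
## implementation; only usable on small inputs.
bruteForceRoh <- function(g, pos, p = rohParams()) {
  n <- length(g)
  w <- p$windowSnps
  out <- data.frame(first = integer(0), last = integer(0))
  if (n < w) return(out)
  nWin <- n - w + 1
  winOK <- logical(nWin)
  for (s in seq_len(nWin)) {
    win <- g[s:(s + w - 1)]
    winOK[s] <- sum(!is.na(win) & win == 1) <= p$windowHetMax &&
      sum(is.na(win)) <= p$windowMissingMax
  }
  qual <- logical(n)
  for (i in seq_len(n)) {
    spans <- intersect(seq_len(nWin), (i - w + 1):i)
    qual[i] <- mean(winOK[spans]) >= p$windowHitThreshold
  }
  i <- 1
  while (i <= n) {
    if (!qual[i]) { i <- i + 1; next }
    j <- i
    while (j < n && qual[j + 1]) j <- j + 1
    ## split the run [i, j] at gaps, then check each piece
    a <- i
    for (k in i:j) {
      gapAfter <- k < j && (pos[k + 1] - pos[k]) > p$maxGapKb * 1000
      if (gapAfter || k == j) {
        b <- k
        ns <- b - a + 1
        len <- pos[b] - pos[a] + 1
        if (ns >= p$minSnps && len >= p$minKb * 1000 &&
            (len / 1000) / ns <= p$minDensityKbPerSnp)
          out <- rbind(out, data.frame(first = a, last = b))
        a <- k + 1
      }
    }
    i <- j + 1
  }
  out
}

## callROH result as a comparable first/last-index table on one chromosome
rohIndexTable <- function(gr, pos) {
  if (!length(gr)) return(data.frame(first = integer(0), last = integer(0)))
  data.frame(first = match(GenomicRanges::start(gr), pos),
             last = match(GenomicRanges::end(gr), pos))
}

## toy single-chromosome panel with evenly spaced SNPs
toyPanel <- function(n, spacingBp = 10000, freq = 0.5) {
  L <- (n + 1) * spacingBp
  map <- makeGeneticMap(nChrom = 1, physicalLengthsBp = L,
                       geneticLengthsCm = max(1, L / 1e6),
                       heterogeneity = 0)
  new("SnpPanel", map = map, chromIdx = rep(1L, n),
      posBp = seq(spacingBp, by = spacingBp, length.out = n),
      freq = rep(freq, n), mafFloor = 0.05)
}
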