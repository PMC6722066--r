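## Bulk cohort simulators. These are the workhorses behind the
## reproduction experiments: segment-level cohorts (origin tilings only,
## no genotypes) for HBD segment-count and length-distribution work, and
## genotype-level cohorts (materialized genotypes, error injection, ROH
## calling) for the classification experiments.

#' Simulate a segment-level cohort of inbred offspring
#'
#' Runs `n` independent pedigrees of the given mating type, tracking
#' founder-origin labels only (no genotypes), and extracts true HBD
#' segments from each terminal offspring.
#'
#' @param type mating-type code (PO, FS, HS, AV, GP, DC, FC, UN).
#' @param n number of replicates.
#' @param map a [GeneticMap-class].
#' @param collectLengths pool all HBD segment lengths across replicates?
#' @param perIndividual additionally keep each replicate's own length
#'   vector?
#' @param seed optional integer seed.
#' @return list with `stats` (data.frame: `rep`, `nSegments`,
#'   `hbdFraction`) and, when requested, `lengthsMb` (pooled segment
#'   lengths in Mb) and `perIndividual` (list of per-replicate length
#'   vectors).
#' @examples
#' map <- makeGeneticMap(seed = 1)
#' res <- simulateHbdCohort("FC", 50, map, seed = 2)
#' mean(res$stats$nSegments)   # ~14.9 at full scale
#' @export
simulateHbdCohort <- function(type, n, map, collectLengths = TRUE,
                              perIndividual = FALSE, seed = NULL) {
  type <- match.arg(type, .MATING_TYPES)
  if (!is.null(seed)) set.seed(seed)
  mi <- .mapIntervals(map)
  need <- .MATING_NFOUNDERS[[type]]
  labs <- lapply(seq_len(need), function(f) c(2L * f - 1L, 2L * f))
  counts <- integer(n); fracs <- numeric(n)
  keepLens <- collectLengths || perIndividual
  lens <- if (keepLens) vector("list", n) else NULL
  for (i in seq_len(n)) {
    term <- .runPedigree(type, mi, labs)
    iv <- .hbdIntervals(term$t1, term$t2, mi)
    counts[i] <- length(iv$start)
    fracs[i] <- sum(iv$end - iv$start) / mi$totalBp
    if (keepLens) lens[[i]] <- (iv$end - iv$start) / 1e6
  }
  out <- list(stats = data.frame(rep = seq_len(n), nSegments = counts,
                                 hbdFraction = fracs),
              type = type, seed = seed)
  if (collectLengths) out$lengthsMb <- unlist(lens)
  if (perIndividual) out$perIndividual <- lens
  out
}

#' Simulate a genotype-level cohort with ROH calling
#'
#' For each replicate: draws founders from the panel, runs the pedigree,
#' materializes offspring genotypes, injects genotyping errors, calls
#' ROHs and summarizes the inbreeding profile.
#'
#' @param type mating-type code.
#' @param n number of replicates.
#' @param founders a [FounderPanel-class].
#' @param params a [rohParams()] list.
#' @param errorRate overall genotyping error rate (NULL disables error
#'   injection). The default 4.5e-4 matches array error at
#'   quality-controlled SNPs.
#' @param denominatorMb autosome length for F_ROH.
#' @param collectLengths pool detected ROH lengths across replicates?
#' @param perIndividualLengths additionally keep each replicate's ROH
#'   length vector (list column is expensive; off by default).
#' @param computeFuni compute F_UNI per replicate?
#' @param seed optional integer seed.
#' @return list with `profiles` (data.frame: `rep`, `type`, `fROH`,
#'   `nROH`, `meanLengthMb`, `trueHbdFraction`, optionally `fUNI`) plus
#'   optional `lengthsMb` and `perIndividual` (list of length vectors).
#' @export
simulateRohCohort <- function(type, n, founders, params = rohParams(),
                              errorRate = 4.5e-4, denominatorMb = 2881,
                              collectLengths = FALSE,
                              perIndividualLengths = FALSE,
                              computeFuni = FALSE, seed = NULL) {
  type <- match.arg(type, .MATING_TYPES)
  if (!is.null(seed)) set.seed(seed)
  panel <- founders@panel
  mi <- .mapIntervals(panel@map)
  snpG <- .snpGenomePos(panel)
  nsnp <- length(snpG)
  sidx <- seq_len(nsnp)
  need <- .MATING_NFOUNDERS[[type]]
  nf <- nFounders(founders)
  if (nf < need)
    stop(sprintf("mating type %s needs %d founders, panel has %d",
                 type, need, nf))
  chromOfSnp <- panel@chromIdx
  chroms <- unique(chromOfSnp)
  snpSel <- lapply(chroms, function(ci) which(chromOfSnp == ci))
  posSel <- lapply(snpSel, function(s) panel@posBp[s])
  nChromSnps <- lengths(snpSel)

  fROH <- numeric(n); nROH <- integer(n); meanL <- numeric(n)
  hbdF <- numeric(n); funi <- numeric(n)
  lens <- if (collectLengths || perIndividualLengths) vector("list", n)
  for (i in seq_len(n)) {
    fidx <- sample.int(nf, need)
    labs <- lapply(fidx, function(f) c(2L * f - 1L, 2L * f))
    term <- .runPedigree(type, mi, labs)
    i1 <- findInterval(snpG, term$t1$e, left.open = TRUE) + 1L
    i2 <- findInterval(snpG, term$t2$e, left.open = TRUE) + 1L
    geno <- as.integer(founders@haplo[cbind(sidx, term$t1$l[i1])]) +
            as.integer(founders@haplo[cbind(sidx, term$t2$l[i2])])
    if (!is.null(errorRate) && errorRate > 0) {
      for (k in seq_along(chroms)) {
        nerr <- rpois(1, errorRate * nChromSnps[k])
        if (nerr == 0) next
        nerr <- min(nerr, nChromSnps[k])
        at <- snpSel[[k]][sample.int(nChromSnps[k], nerr)]
        geno[at] <- (geno[at] +
                       sample.int(2L, nerr, replace = TRUE)) %% 3L
      }
    }
    tot <- 0; cnt <- 0L; ls <- numeric(0)
    for (k in seq_along(chroms)) {
      runs <- .rohScanChrom(geno[snpSel[[k]]], posSel[[k]], params)
      if (length(runs$first)) {
        lkb <- posSel[[k]][runs$last] - posSel[[k]][runs$first] + 1
        tot <- tot + sum(lkb)
        cnt <- cnt + length(lkb)
        if (collectLengths || perIndividualLengths)
          ls <- c(ls, lkb / 1e6)
      }
    }
    fROH[i] <- tot / 1e6 / denominatorMb
    nROH[i] <- cnt
    meanL[i] <- if (cnt) tot / 1e6 / cnt else NA_real_
    iv <- .hbdIntervals(term$t1, term$t2, mi)
    hbdF[i] <- sum(iv$end - iv$start) / mi$totalBp
    if (computeFuni) funi[i] <- fUNI(geno, panel@freq)
    if (collectLengths || perIndividualLengths) lens[[i]] <- ls
  }
  profiles <- data.frame(rep = seq_len(n), type = type, fROH = fROH,
                         nROH = nROH, meanLengthMb = meanL,
                         trueHbdFraction = hbdF)
  if (computeFuni) profiles$fUNI <- funi
  out <- list(profiles = profiles, seed = seed)
  if (collectLengths) out$lengthsMb <- unlist(lens)
  if (perIndividualLengths) out$perIndividual <- lens
  out
}

#' Mean detected ROH count in offspring of unrelated founders
#'
#' Calibration / verification helper for background relatedness: simulates
#' offspring of random founder pairs (UN matings) and returns their mean
#' number of detected ROHs.
#'
#' @param founders a [FounderPanel-class].
#' @param nOffspring number of UN offspring to simulate.
#' @param params a [rohParams()] list.
#' @param errorRate overall genotyping error rate.
#' @param seed optional integer seed.
#' @return numeric(1), mean N_ROH.
#' @export
meanUnRohCount <- function(founders, nOffspring = 60, params = rohParams(),
                           errorRate = 4.5e-4, seed = NULL) {
  res <- simulateRohCohort("UN", nOffspring, founders, params = params,
                           errorRate = errorRate, seed = seed)
  mean(res$profiles$nROH)
}
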