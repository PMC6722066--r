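## Meiosis engine. Haplotypes are "tilings": half-open interval lists on a
## concatenated genome coordinate (list(e = segment end positions, l =
## integer founder-haplotype labels); segment i covers (e[i-1], e[i]]).
## Recombination follows the Bernoulli-per-map-interval scheme: each map
## interval independently receives a breakpoint with probability
## min(1, interval genetic length in Morgans); the breakpoint position is
## uniform within the interval. The starting haplotype of each chromosome
## is a fair coin, implemented as a Bernoulli(1/2) phase switch at each
## chromosome start. There is no crossover interference.

.MATING_TYPES <- c("PO", "FS", "HS", "AV", "GP", "DC", "FC", "UN")
.MATING_CLASS <- c(PO = "MT1", FS = "MT1", HS = "MT2", AV = "MT2",
                   GP = "MT2", DC = "MT2", FC = "MT3", UN = "UN")
.MATING_F <- c(PO = 0.25, FS = 0.25, HS = 0.125, AV = 0.125,
               GP = 0.125, DC = 0.125, FC = 0.0625, UN = 0)
.MATING_NFOUNDERS <- c(PO = 2, FS = 2, HS = 3, AV = 3, GP = 3, DC = 4,
                       FC = 4, UN = 2)

#' Mating-type metadata
#'
#' The eight simulated pedigrees: parent-offspring (PO), full sibs (FS),
#' half sibs (HS), avuncular (AV), grandparent-grandchild (GP), double
#' first cousins (DC), first cousins (FC) and unrelated (UN). Meta-classes
#' group them by expected offspring inbreeding coefficient: MT1 = {PO, FS}
#' (F = 1/4), MT2 = {HS, AV, GP, DC} (F = 1/8), MT3 = {FC} (F = 1/16).
#'
#' @param type character vector of mating-type codes.
#' @return `matingClass`: the meta-class; `expectedF`: the pedigree
#'   expectation of the offspring inbreeding coefficient.
#' @examples
#' matingClass(c("PO", "GP", "FC"))
#' expectedF("FC")  # 0.0625
#' @export
matingClass <- function(type) unname(.MATING_CLASS[match.arg(type, .MATING_TYPES, several.ok = TRUE)])

#' @rdname matingClass
#' @export
expectedF <- function(type) unname(.MATING_F[match.arg(type, .MATING_TYPES, several.ok = TRUE)])

.founderTiling <- function(mi, lab) {
  list(e = mi$chromEnd, l = rep(as.integer(lab), length(mi$chromEnd)))
}

.compressTiling <- function(e, l, protect) {
  n <- length(e)
  if (n <= 1L) return(list(e = e, l = l))
  drop <- l[-n] == l[-1L] & !(e[-n] %in% protect)
  keep <- c(!drop, TRUE)
  list(e = e[keep], l = l[keep])
}

.meiose <- function(tA, tB, mi) {
  hit <- which(runif(length(mi$pB)) < mi$pB)
  bp <- mi$start[hit] + runif(length(hit)) * mi$width[hit]
  ## fair-coin starting haplotype per chromosome: a phase switch at each
  ## chromosome start; the first chromosome's coin flips the base parity
  ## instead (a switch at coordinate 0 would create a zero-width segment)
  coins <- runif(length(mi$chromStart)) < 0.5
  sw <- sort(c(bp, mi$chromStart[-1][coins[-1]]))
  g <- sort(unique(c(tA$e, tB$e, sw)))
  s <- c(0, g[-length(g)])
  useA <- ((findInterval(s, sw) + coins[1]) %% 2L) == 0L
  lab <- integer(length(s))
  if (any(useA))  lab[useA]  <- tA$l[findInterval(s[useA],  tA$e) + 1L]
  if (any(!useA)) lab[!useA] <- tB$l[findInterval(s[!useA], tB$e) + 1L]
  .compressTiling(g, lab, mi$chromEnd)
}

## Run one pedigree; founderLabs is a list of c(hap1, hap2) label pairs,
## one per founder. Returns list(t1, t2) for the terminal inbred offspring.
.runPedigree <- function(type, mi, founderLabs) {
  Fg <- lapply(founderLabs, function(p)
    list(t1 = .founderTiling(mi, p[1]), t2 = .founderTiling(mi, p[2])))
  names(Fg) <- paste0("F", seq_along(Fg))
  child <- function(p, q)
    list(t1 = .meiose(p$t1, p$t2, mi), t2 = .meiose(q$t1, q$t2, mi))
  switch(type,
    UN = child(Fg$F1, Fg$F2),
    PO = {
      O <- child(Fg$F1, Fg$F2)
      child(O, if (runif(1) < 0.5) Fg$F1 else Fg$F2)
    },
    FS = {
      A <- child(Fg$F1, Fg$F2); B <- child(Fg$F1, Fg$F2)
      child(A, B)
    },
    HS = {
      A <- child(Fg$F1, Fg$F2); B <- child(Fg$F1, Fg$F3)
      child(A, B)
    },
    AV = {
      A <- child(Fg$F1, Fg$F2); B <- child(Fg$F1, Fg$F2)
      C <- child(B, Fg$F3)
      child(A, C)
    },
    GP = {
      A <- child(Fg$F1, Fg$F2); B <- child(A, Fg$F3)
      child(Fg$F1, B)
    },
    DC = {
      A <- child(Fg$F1, Fg$F2); B <- child(Fg$F1, Fg$F2)
      C <- child(Fg$F3, Fg$F4); D <- child(Fg$F3, Fg$F4)
      E <- child(A, C); G <- child(B, D)
      child(E, G)
    },
    FC = {
      A <- child(Fg$F1, Fg$F2); B <- child(Fg$F1, Fg$F2)
      C <- child(A, Fg$F3); D <- child(B, Fg$F4)
      child(C, D)
    },
    stop("unknown mating type: ", type)
  )
}

#' Sample one gamete from a parent genome
#'
#' Draws recombination breakpoints independently per map interval
#' (probability min(1, interval length in Morgans), position uniform within
#' the interval), picks the starting haplotype of each chromosome by a fair
#' coin, and returns the recombined haplotype with its founder-origin
#' labels.
#'
#' @param parent an [OriginGenome-class].
#' @param seed optional integer seed.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp` (half-open
#'   physical interval) and `label` (founder haplotype of origin).
#' @export
sampleGamete <- function(parent, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mi <- .mapIntervals(parent@map)
  g <- .meiose(parent@tiling1, parent@tiling2, mi)
  .tilingToFrame(g, mi)
}

.tilingToFrame <- function(t, mi) {
  s <- c(0, t$e[-length(t$e)])
  ci <- findInterval(s, mi$chromStart)
  data.frame(chrom = mi$chromNames[ci],
             start_bp = s - mi$chromStart[ci],
             end_bp = t$e - mi$chromStart[ci],
             label = t$l)
}

#' Simulate the inbred offspring of a mating type
#'
#' Runs the full pedigree for the requested mating type on founders drawn
#' at random from a founder panel and returns the terminal inbred
#' offspring. For PO, a child of two founders is first simulated and then
#' mated back to one of its parents (chosen at random). Genotypes are
#' materialized from the founder haplotypes unless `withGenotypes = FALSE`.
#'
#' @param type mating-type code, one of PO, FS, HS, AV, GP, DC, FC, UN.
#' @param founders a [FounderPanel-class] with enough founders for the
#'   pedigree (2 for PO/FS/UN, 3 for HS/AV/GP, 4 for DC/FC).
#' @param withGenotypes materialize per-SNP genotypes?
#' @param errorRate overall genotyping error rate applied after
#'   materialization (NULL for none); see [injectGenotypingErrors()].
#' @param seed optional integer seed.
#' @return an [OriginGenome-class].
#' @examples
#' map <- makeGeneticMap(nChrom = 2, physicalLengthsBp = c(6e7, 5e7),
#'                       geneticLengthsCm = c(80, 70), seed = 1)
#' panel <- makeSnpPanel(map, densityPerMb = 30, seed = 2)
#' fp <- makeFounders(panel, n = 4, seed = 3)
#' og <- simulateMating("FS", fp, seed = 4)
#' trueHbdSegments(og)
#' @export
simulateMating <- function(type, founders,
                           withGenotypes = TRUE, errorRate = NULL,
                           seed = NULL) {
  type <- match.arg(type, .MATING_TYPES)
  if (!is.null(seed)) set.seed(seed)
  need <- .MATING_NFOUNDERS[[type]]
  nf <- nFounders(founders)
  if (nf < need)
    stop(sprintf("mating type %s needs %d founders, panel has %d",
                 type, need, nf))
  map <- founders@panel@map
  mi <- .mapIntervals(map)
  fidx <- sample.int(nf, need)
  labs <- lapply(fidx, function(f) c(2L * f - 1L, 2L * f))
  term <- .runPedigree(type, mi, labs)
  og <- new("OriginGenome", map = map, tiling1 = term$t1, tiling2 = term$t2,
            genotypes = integer(0), matingType = type)
  if (withGenotypes) {
    og@genotypes <- offspringGenotypes(og, founders)
    if (!is.null(errorRate))
      og <- injectGenotypingErrors(og, founders@panel, rate = errorRate)
  }
  og
}

#' Materialize per-SNP genotypes from origin tilings
#'
#' Looks up, for every SNP of the founder panel, the founder haplotype each
#' of the two inherited chromosomes descends from, and sums the two founder
#' alleles into a 0/1/2 dosage.
#'
#' @param genome an [OriginGenome-class].
#' @param founders the [FounderPanel-class] the genome was simulated from.
#' @return integer vector of dosages aligned to the panel.
#' @export
offspringGenotypes <- function(genome, founders) {
  panel <- founders@panel
  snpG <- .snpGenomePos(panel)
  i1 <- findInterval(snpG, genome@tiling1$e, left.open = TRUE) + 1L
  i2 <- findInterval(snpG, genome@tiling2$e, left.open = TRUE) + 1L
  sidx <- seq_along(snpG)
  a1 <- as.integer(founders@haplo[cbind(sidx, genome@tiling1$l[i1])])
  a2 <- as.integer(founders@haplo[cbind(sidx, genome@tiling2$l[i2])])
  a1 + a2
}

## Intersect the two haplotype tilings of an individual: maximal intervals
## where both carry the same founder-haplotype label. Returns genome-coord
## start/end pairs (half-open).
.hbdIntervals <- function(t1, t2, mi) {
  g <- sort(unique(c(t1$e, t2$e)))
  s <- c(0, g[-length(g)])
  l1 <- t1$l[findInterval(s, t1$e) + 1L]
  l2 <- t2$l[findInterval(s, t2$e) + 1L]
  eq <- l1 == l2
  if (!any(eq))
    return(list(start = numeric(0), end = numeric(0)))
  idx <- which(eq)
  if (length(idx) > 1L) {
    contiguous <- diff(idx) == 1L &
      !(g[idx[-length(idx)]] %in% mi$chromEnd) &
      l1[idx[-1L]] == l1[idx[-length(idx)]]
    brk <- c(TRUE, !contiguous)
  } else brk <- TRUE
  firsts <- which(brk)
  lasts <- c(firsts[-1L] - 1L, length(idx))
  list(start = s[idx[firsts]], end = g[idx[lasts]])
}

#' Extract true homozygosity-by-descent segments
#'
#' Maximal intervals where the two inherited haplotypes carry the same
#' founder-haplotype label, i.e. autozygosity within the simulated
#' pedigree. No minimum-length filter is applied; callers may subset on
#' the `lengthMb` metadata column.
#'
#' @param genome an [OriginGenome-class].
#' @return a [GenomicRanges::GRanges] with metadata columns `kind` ("HBD")
#'   and `lengthMb`.
#' @export
trueHbdSegments <- function(genome) {
  mi <- .mapIntervals(genome@map)
  iv <- .hbdIntervals(genome@tiling1, genome@tiling2, mi)
  .intervalsToGRanges(iv$start, iv$end, mi, kind = "HBD")
}

.intervalsToGRanges <- function(startG, endG, mi, kind, nSnps = NULL) {
  if (!length(startG)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$kind <- character(0)
    S4Vectors::mcols(gr)$lengthMb <- numeric(0)
    if (!is.null(nSnps)) S4Vectors::mcols(gr)$nSnps <- integer(0)
    return(gr)
  }
  ci <- findInterval(startG, mi$chromStart)
  gr <- GenomicRanges::GRanges(
    seqnames = mi$chromNames[ci],
    ranges = IRanges::IRanges(
      start = floor(startG - mi$chromStart[ci]) + 1,
      end = ceiling(endG - mi$chromStart[ci])))
  S4Vectors::mcols(gr)$kind <- kind
  S4Vectors::mcols(gr)$lengthMb <- (endG - startG) / 1e6
  if (!is.null(nSnps)) S4Vectors::mcols(gr)$nSnps <- nSnps
  gr
}

#' True HBD fraction of a simulated genome
#'
#' Total length of true HBD segments divided by the autosomal physical
#' length of the genome's map.
#'
#' @param genome an [OriginGenome-class].
#' @return numeric(1) in [0, 1].
#' @export
trueHbdFraction <- function(genome) {
  mi <- .mapIntervals(genome@map)
  iv <- .hbdIntervals(genome@tiling1, genome@tiling2, mi)
  sum(iv$end - iv$start) / mi$totalBp
}

#' Inject genotyping errors
#'
#' Per chromosome, draws a Poisson(rate x SNP count) number of SNPs
#' (uniformly, without replacement) and replaces each genotype with a
#' uniformly chosen different value in {0, 1, 2}. The default overall rate
#' of 4.5e-4 reflects array genotyping error at quality-controlled SNPs.
#'
#' @param x an [OriginGenome-class] with materialized genotypes, or an
#'   integer genotype vector aligned to `panel`.
#' @param panel the [SnpPanel-class] the genotypes align to.
#' @param rate overall error rate, recycled per chromosome unless
#'   `perChromRates` is given.
#' @param perChromRates optional numeric vector of per-chromosome rates
#'   (one per autosome of the panel's map).
#' @param seed optional integer seed.
#' @return same type as `x`, with errors applied.
#' @export
injectGenotypingErrors <- function(x, panel, rate = 4.5e-4,
                                   perChromRates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- if (is(x, "OriginGenome")) x@genotypes else x
  if (!length(geno)) stop("no genotypes to perturb")
  if (length(geno) != nSnps(panel)) stop("genotypes do not align to panel")
  chroms <- unique(panel@chromIdx)
  if (is.null(perChromRates)) perChromRates <- rep(rate, length(chroms))
  if (length(perChromRates) != length(chroms))
    stop("perChromRates must have one entry per chromosome")
  if (any(perChromRates < 0)) stop("error rates must be >= 0")
  for (k in seq_along(chroms)) {
    sel <- which(panel@chromIdx == chroms[k])
    nerr <- rpois(1, perChromRates[k] * length(sel))
    if (nerr == 0) next
    nerr <- min(nerr, length(sel))
    at <- sel[sample.int(length(sel), nerr)]
    old <- geno[at]
    shift <- sample.int(2L, nerr, replace = TRUE)  # +1 or +2 mod 3
    geno[at] <- (old + shift) %% 3L
  }
  if (is(x, "OriginGenome")) { x@genotypes <- geno; x } else geno
}
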