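#' Sample a SNP genotyping panel over a genetic map
#'
#' Draws SNP positions uniformly along each autosome (per-chromosome counts
#' are Poisson with mean `densityPerMb` x length in Mb) and assigns each SNP
#' a population allele frequency whose minor-allele frequency is uniform on
#' `[mafFloor, 0.5]`, with the counted allele chosen at random. The default
#' density, 301,412 / 2881 Mb, emulates a quality-controlled genotyping
#' array after a MAF > 5% filter.
#'
#' @param map a [GeneticMap-class]. Only autosomes receive SNPs.
#' @param densityPerMb expected SNPs per Mb.
#' @param mafFloor minimum minor allele frequency, in (0, 0.5).
#' @param seed integer seed.
#' @return a [SnpPanel-class].
#' @examples
#' map <- makeGeneticMap(nChrom = 2, physicalLengthsBp = c(5e7, 4e7),
#'                       geneticLengthsCm = c(60, 50), seed = 1)
#' panel <- makeSnpPanel(map, densityPerMb = 20, seed = 1)
#' @export
makeSnpPanel <- function(map, densityPerMb = 301412 / 2881,
                         mafFloor = 0.05, seed = NULL) {
  if (densityPerMb <= 0) stop("densityPerMb must be positive")
  if (mafFloor <= 0 || mafFloor >= 0.5) stop("mafFloor must be in (0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  idx <- .autosomeIdx(map)
  chromIdx <- integer(0); posBp <- numeric(0)
  for (k in seq_along(idx)) {
    i <- idx[k]
    lenMb <- map@lengthsBp[i] / 1e6
    n <- rpois(1, densityPerMb * lenMb)
    n <- min(n, floor(map@lengthsBp[i]))
    pos <- sort(sample.int(as.integer(map@lengthsBp[i]), n))
    chromIdx <- c(chromIdx, rep(i, n))
    posBp <- c(posBp, pos)
  }
  maf <- runif(length(posBp), mafFloor, 0.5)
  flip <- runif(length(posBp)) < 0.5
  freq <- ifelse(flip, 1 - maf, maf)
  new("SnpPanel", map = map, chromIdx = as.integer(chromIdx),
      posBp = posBp, freq = freq, mafFloor = mafFloor)
}

#' Number of SNPs in a panel
#' @param panel a [SnpPanel-class].
#' @return integer(1).
#' @export
nSnps <- function(panel) length(panel@posBp)

#' SNP table of a panel
#'
#' @param panel a [SnpPanel-class].
#' @return data.frame with columns `chrom`, `pos_bp`, `freq`.
#' @export
snpTable <- function(panel) {
  data.frame(chrom = panel@map@chromNames[panel@chromIdx],
             pos_bp = panel@posBp, freq = panel@freq)
}

## SNP positions on the concatenated autosomal coordinate used by the
## meiosis engine; must share .mapIntervals()'s chromosome offsets.
.snpGenomePos <- function(panel) {
  mi <- .mapIntervals(panel@map)
  aidx <- .autosomeIdx(panel@map)
  off <- setNames(mi$chromStart, aidx)
  panel@posBp + off[as.character(panel@chromIdx)]
}
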