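## Default calibration constant for background relatedness: size of the
## ancestral haplotype pool from which founder haplotypes are mosaics.
## Chosen (together with the 25-generation depth) so that offspring of two
## random founders carry ~4.8 detectable ROHs > 1.5 Mb on the default
## genome; see the methods vignette for the calibration sweep.
.BG_POOL_DEFAULT <- 100L
.BG_GENERATIONS_DEFAULT <- 25L

#' Generate founder haplotypes over a SNP panel
#'
#' With `background = "off"`, founder haplotypes are independent draws from
#' the panel allele frequencies (no shared ancestry), so offspring of two
#' founders have no long homozygous tracts beyond chance. With
#' `background = "calibrated"`, each founder haplotype is a mosaic of a
#' small pool of `poolSize` ancestral haplotypes, with tract breakpoints
#' laid down at `generations` meioses' worth of recombination density. Two
#' "unrelated" founders then share ancestral tracts of a few cM, emulating
#' distant common ancestry: offspring of random founder pairs average about
#' 4.8 ROHs > 1.5 Mb under the default pool size.
#'
#' @param panel a [SnpPanel-class].
#' @param n number of founders (>= 2).
#' @param background `"off"` or `"calibrated"`.
#' @param poolSize ancestral haplotype pool size (calibration constant).
#' @param generations depth of the mosaic process in meioses.
#' @param seed integer seed.
#' @param verify simulate `verifyN` offspring of unrelated founder pairs,
#'   call ROHs, and fail if their mean ROH count falls outside [3.8, 5.8]
#'   (only meaningful with calibrated background).
#' @param verifyN number of verification offspring.
#' @return a [FounderPanel-class]; calibration constants are recorded in
#'   its `calibration` slot.
#' @export
makeFounders <- function(panel, n, background = c("off", "calibrated"),
                         poolSize = .BG_POOL_DEFAULT,
                         generations = .BG_GENERATIONS_DEFAULT,
                         seed = NULL, verify = FALSE, verifyN = 60) {
  background <- match.arg(background)
  if (n < 2) stop("need at least 2 founders")
  if (!is.null(seed)) set.seed(seed)
  nsnp <- nSnps(panel)
  H <- 2L * as.integer(n)
  haplo <- matrix(raw(0), nrow = nsnp, ncol = H)
  calibration <- list()

  if (background == "off") {
    for (h in seq_len(H))
      haplo[, h] <- as.raw(rbinom(nsnp, 1L, panel@freq))
  } else {
    if (poolSize < 2) stop("poolSize must be >= 2")
    ## ancestral pool alleles
    anc <- matrix(raw(0), nrow = nsnp, ncol = poolSize)
    for (k in seq_len(poolSize))
      anc[, k] <- as.raw(rbinom(nsnp, 1L, panel@freq))
    mi <- .mapIntervals(panel@map)
    snpG <- .snpGenomePos(panel)
    pBreak <- pmin(1, generations * mi$dM)
    for (h in seq_len(H)) {
      hit <- which(runif(length(pBreak)) < pBreak)
      bp <- mi$start[hit] + runif(length(hit)) * mi$width[hit]
      ends <- sort(c(bp, mi$chromEnd))
      labs <- sample.int(poolSize, length(ends), replace = TRUE)
      seg <- findInterval(snpG, ends, left.open = TRUE) + 1L
      haplo[, h] <- anc[cbind(seq_len(nsnp), labs[seg])]
    }
    calibration <- list(poolSize = as.integer(poolSize),
                        generations = as.integer(generations))
  }

  fp <- new("FounderPanel", panel = panel, haplo = haplo,
            background = background, calibration = calibration)
  if (verify && background == "calibrated") {
    m <- meanUnRohCount(fp, nOffspring = verifyN)
    fp@calibration$verifiedMeanNRoh <- m
    if (m < 3.8 || m > 5.8)
      stop(sprintf(paste0("background calibration failed: mean N_ROH of ",
                          "unrelated-mating offspring = %.2f, outside [3.8, 5.8]"), m))
  }
  fp
}

#' Number of founders in a panel
#' @param founders a [FounderPanel-class].
#' @return integer(1).
#' @export
nFounders <- function(founders) ncol(founders@haplo) %/% 2L

#' Founder haplotype alleles
#'
#' @param founders a [FounderPanel-class].
#' @param labels haplotype labels (column indices); default all.
#' @return integer 0/1 matrix, SNPs x haplotypes.
#' @export
founderHaplotypes <- function(founders, labels = NULL) {
  if (is.null(labels)) labels <- seq_len(ncol(founders@haplo))
  m <- matrix(as.integer(founders@haplo[, labels, drop = FALSE]),
              nrow = nrow(founders@haplo))
  colnames(m) <- labels
  m
}

#' Founder genotype dosages
#'
#' @param founders a [FounderPanel-class].
#' @return integer 0/1/2 matrix, SNPs x founders.
#' @export
founderGenotypes <- function(founders) {
  H <- ncol(founders@haplo)
  i1 <- seq(1L, H, by = 2L)
  m <- matrix(as.integer(founders@haplo[, i1]) +
                as.integer(founders@haplo[, i1 + 1L]),
              nrow = nrow(founders@haplo))
  colnames(m) <- seq_len(H %/% 2L)
  m
}

#' Empirical allele frequencies across founders
#' @param founders a [FounderPanel-class].
#' @return numeric vector, one frequency per SNP.
#' @export
founderFrequencies <- function(founders) {
  nsnp <- nrow(founders@haplo)
  tot <- numeric(nsnp)
  for (h in seq_len(ncol(founders@haplo)))
    tot <- tot + as.integer(founders@haplo[, h])
  tot / ncol(founders@haplo)
}
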