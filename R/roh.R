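#' ROH caller parameters
#'
#' Parameters of the sliding-window ROH scan, mirroring the conventional
#' genotype-based ROH detection settings: scanning windows of `windowSnps`
#' consecutive SNPs are "homozygous" if they contain at most `windowHetMax`
#' heterozygous and `windowMissingMax` missing calls; a SNP qualifies when
#' at least a fraction `windowHitThreshold` of the windows spanning it are
#' homozygous; maximal runs of qualifying SNPs are reported if they span at
#' least `minKb` kb and `minSnps` SNPs, contain no inter-SNP gap above
#' `maxGapKb` kb, and average at most `minDensityKbPerSnp` kb per SNP.
#'
#' @param minKb minimum ROH length in kb (1500 by default; 2000 and 5000
#'   reproduce the sensitivity analyses).
#' @param minSnps minimum number of SNPs in an ROH.
#' @param windowSnps scanning window size in SNPs.
#' @param windowHetMax maximum heterozygous calls per window.
#' @param windowMissingMax maximum missing calls per window.
#' @param maxGapKb maximum gap between consecutive ROH SNPs in kb.
#' @param minDensityKbPerSnp maximum average kb per SNP within an ROH.
#' @param windowHitThreshold minimum fraction of spanning homozygous
#'   windows for a SNP to qualify.
#' @return a named list of class `RohParams`.
#' @export
rohParams <- function(minKb = 1500, minSnps = 50, windowSnps = 50,
                      windowHetMax = 1, windowMissingMax = 5,
                      maxGapKb = 1000, minDensityKbPerSnp = 50,
                      windowHitThreshold = 0.05) {
  p <- list(minKb = minKb, minSnps = minSnps, windowSnps = windowSnps,
            windowHetMax = windowHetMax, windowMissingMax = windowMissingMax,
            maxGapKb = maxGapKb, minDensityKbPerSnp = minDensityKbPerSnp,
            windowHitThreshold = windowHitThreshold)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1, TRUE)))
  if (any(unlist(p[c("minKb", "minSnps", "windowSnps", "maxGapKb",
                     "minDensityKbPerSnp", "windowHitThreshold")]) <= 0))
    stop("ROH parameters must be positive")
  class(p) <- c("RohParams", "list")
  p
}

## Vectorized single-chromosome scan; g is 0/1/2/NA, pos strictly increasing.
.rohScanChrom <- function(g, pos, p) {
  n <- length(g)
  w <- p$windowSnps
  empty <- list(first = integer(0), last = integer(0))
  if (n < max(w, p$minSnps)) return(empty)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  csH <- c(0, cumsum(het))
  csM <- c(0, cumsum(mis))
  W <- n - w + 1L
  starts <- seq_len(W)
  winOK <- (csH[starts + w] - csH[starts]) <= p$windowHetMax &
           (csM[starts + w] - csM[starts]) <= p$windowMissingMax
  csW <- c(0, cumsum(winOK))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(W, i)
  qual <- (csW[hi + 1L] - csW[lo]) / (hi - lo + 1L) >= p$windowHitThreshold
  if (!any(qual)) return(empty)
  ## maximal runs of qualifying SNPs, split at large physical gaps
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- which(r$values)
  first <- integer(0); last <- integer(0)
  gapBp <- p$maxGapKb * 1000
  for (k in keep) {
    a <- begs[k]; b <- ends[k]
    if (b - a + 1L < p$minSnps) next
    cut <- which(diff(pos[a:b]) > gapBp)
    subBeg <- c(a, a + cut)
    subEnd <- c(a + cut - 1L, b)
    for (j in seq_along(subBeg)) {
      ns <- subEnd[j] - subBeg[j] + 1L
      if (ns < p$minSnps) next
      lenBp <- pos[subEnd[j]] - pos[subBeg[j]] + 1
      if (lenBp < p$minKb * 1000) next
      if ((lenBp / 1000) / ns > p$minDensityKbPerSnp) next
      first <- c(first, subBeg[j]); last <- c(last, subEnd[j])
    }
  }
  list(first = first, last = last)
}

#' Call runs of homozygosity for one individual
#'
#' Sliding-window scan over each chromosome of the panel (see
#' [rohParams()] for the qualification rule). Segment boundaries are the
#' positions of the first and last qualifying SNPs; lengths are
#' end - start + 1 bp. Deterministic for fixed input.
#'
#' @param genotypes integer vector of 0/1/2 dosages (NA = missing) aligned
#'   to `panel`.
#' @param panel a [SnpPanel-class].
#' @param params a [rohParams()] list.
#' @return a [GenomicRanges::GRanges] with metadata columns `kind` ("ROH"),
#'   `lengthMb` and `nSnps`.
#' @examples
#' map <- makeGeneticMap(nChrom = 1, physicalLengthsBp = 2e7,
#'                       geneticLengthsCm = 20, heterogeneity = 0, seed = 1)
#' panel <- makeSnpPanel(map, densityPerMb = 100, seed = 1)
#' g <- rep(0L, nSnps(panel))           # fully homozygous chromosome
#' callROH(g, panel)                    # one ROH spanning the chromosome
#' @export
callROH <- function(genotypes, panel, params = rohParams()) {
  if (length(genotypes) != nSnps(panel))
    stop("genotypes do not align to panel")
  if (!inherits(params, "RohParams")) params <- do.call(rohParams, params)
  chroms <- unique(panel@chromIdx)
  seqn <- character(0); st <- numeric(0); en <- numeric(0); ns <- integer(0)
  for (ci in chroms) {
    sel <- which(panel@chromIdx == ci)
    pos <- panel@posBp[sel]
    if (is.unsorted(pos, strictly = TRUE))
      stop("SNP positions must be strictly increasing within chromosomes")
    runs <- .rohScanChrom(genotypes[sel], pos, params)
    if (length(runs$first)) {
      seqn <- c(seqn, rep(panel@map@chromNames[ci], length(runs$first)))
      st <- c(st, pos[runs$first])
      en <- c(en, pos[runs$last])
      ns <- c(ns, runs$last - runs$first + 1L)
    }
  }
  if (!length(st)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$kind <- character(0)
    S4Vectors::mcols(gr)$lengthMb <- numeric(0)
    S4Vectors::mcols(gr)$nSnps <- integer(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(seqn, IRanges::IRanges(start = st, end = en))
  S4Vectors::mcols(gr)$kind <- "ROH"
  S4Vectors::mcols(gr)$lengthMb <- (en - st + 1) / 1e6
  S4Vectors::mcols(gr)$nSnps <- ns
  gr
}

.segmentLengthsMb <- function(segments) {
  if (!length(segments)) return(numeric(0))
  mc <- S4Vectors::mcols(segments)
  if (!is.null(mc$lengthMb)) mc$lengthMb
  else GenomicRanges::width(segments) / 1e6
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Cumulative ROH length in Mb divided by the autosome length (2881 Mb by
#' default, the hg19 autosomal total the default genome scaffold matches).
#'
#' @param segments a GRanges of disjoint autosomal ROH segments.
#' @param denominatorMb autosome length in Mb.
#' @return numeric(1) in [0, 1].
#' @export
fROH <- function(segments, denominatorMb = 2881) {
  if (length(segments) > 1) {
    ov <- GenomicRanges::findOverlaps(segments, drop.self = TRUE)
    if (length(ov)) stop("ROH segments must be disjoint")
  }
  sum(.segmentLengthsMb(segments)) / denominatorMb
}

#' X-chromosome inbreeding coefficient of a female
#'
#' @param segments a GRanges of ROH segments on the X of a female.
#' @param denominatorMb X-chromosome length in Mb (155 by default).
#' @param sex must be "female"; F_ROH-X is undefined for hemizygous males.
#' @return numeric(1) in [0, 1].
#' @export
fROHX <- function(segments, denominatorMb = 155, sex = "female") {
  if (!identical(sex, "female"))
    stop("F_ROH-X is defined for females only")
  sum(.segmentLengthsMb(segments)) / denominatorMb
}

#' SNP-based inbreeding estimator F_UNI
#'
#' The correlation between uniting gametes, averaged over SNPs: per SNP
#' with dosage x and counted-allele frequency p, the contribution is
#' (x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p)). Missing genotypes are
#' skipped. The expectation is 0 under Hardy-Weinberg equilibrium and the
#' pedigree inbreeding coefficient under inbreeding.
#'
#' @param genotypes integer 0/1/2 dosages (NA = missing).
#' @param freq counted-allele frequencies in (0, 1), one per SNP.
#' @return numeric(1), unbounded (negative values indicate heterozygote
#'   excess).
#' @export
fUNI <- function(genotypes, freq) {
  if (length(genotypes) != length(freq))
    stop("genotypes and freq must align")
  if (any(freq <= 0 | freq >= 1))
    stop("allele frequencies must be strictly inside (0, 1)")
  ok <- !is.na(genotypes)
  x <- genotypes[ok]; p <- freq[ok]
  mean((x^2 - (1 + 2 * p) * x + 2 * p^2) / (2 * p * (1 - p)))
}

#' Per-individual inbreeding profile
#'
#' Calls ROHs and summarizes them into the classifier inputs: F_ROH, the
#' ROH count N_ROH, the mean ROH length, and F_UNI.
#'
#' @param genotypes integer 0/1/2 dosages aligned to `panel`.
#' @param panel a [SnpPanel-class].
#' @param params a [rohParams()] list.
#' @param denominatorMb autosome length for F_ROH.
#' @param id individual identifier.
#' @return one-row data.frame with columns `id`, `fROH`, `nROH`,
#'   `meanLengthMb`, `fUNI`; the ROH GRanges is attached as attribute
#'   `"segments"`.
#' @export
inbreedingProfile <- function(genotypes, panel, params = rohParams(),
                              denominatorMb = 2881, id = NA_character_) {
  seg <- callROH(genotypes, panel, params)
  len <- .segmentLengthsMb(seg)
  out <- data.frame(id = id,
                    fROH = sum(len) / denominatorMb,
                    nROH = length(seg),
                    meanLengthMb = if (length(len)) mean(len) else NA_real_,
                    fUNI = fUNI(genotypes, panel@freq))
  attr(out, "segments") <- seg
  out
}

#' Convert ROH segments to a .hom-style table
#'
#' @param segments GRanges of ROH segments (with `nSnps` metadata).
#' @param iid,fid individual / family identifiers.
#' @return data.frame with columns FID, IID, CHR, POS1, POS2, KB, NSNP,
#'   DENSITY.
#' @export
homTable <- function(segments, iid = "1", fid = iid) {
  ns <- S4Vectors::mcols(segments)$nSnps
  if (is.null(ns)) ns <- NA_integer_
  kb <- (GenomicRanges::end(segments) - GenomicRanges::start(segments) + 1) / 1000
  data.frame(FID = fid, IID = iid,
             CHR = as.character(GenomicRanges::seqnames(segments)),
             POS1 = GenomicRanges::start(segments),
             POS2 = GenomicRanges::end(segments),
             KB = kb, NSNP = ns, DENSITY = kb / ns)
}

#' Write / read .hom-style ROH tables
#'
#' Whitespace-delimited text with the columns of [homTable()].
#'
#' @param hom a data.frame from [homTable()] (several individuals may be
#'   row-bound).
#' @param path file path.
#' @return `readHom` returns the data.frame.
#' @export
writeHom <- function(hom, path) {
  write.table(hom, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHom
#' @export
readHom <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c(CHR = "character"))
}

#' Write / read a transposed tabular genotype matrix
#'
#' Rows are SNPs: `chrom`, `pos_bp`, then one dosage column per individual.
#'
#' @param geno integer matrix, SNPs x individuals.
#' @param panel the [SnpPanel-class] the rows align to.
#' @param path file path.
#' @return `readGenotypes` returns a list with elements `chrom`, `pos_bp`
#'   and `geno` (integer matrix).
#' @export
writeGenotypes <- function(geno, panel, path) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) colnames(geno) <- seq_len(ncol(geno))
  df <- data.frame(chrom = panel@map@chromNames[panel@chromIdx],
                   pos_bp = panel@posBp)
  df <- cbind(df, as.data.frame(geno))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(chrom = "character"))
  list(chrom = df$chrom, pos_bp = df$pos_bp,
       geno = as.matrix(df[, -(1:2), drop = FALSE]))
}
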