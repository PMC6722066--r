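## Embedded default genome scaffold: per-chromosome physical lengths (Mb)
## approximating the hg19 autosomes and sex-averaged genetic lengths (cM).
## Both vectors are rescaled at map construction so the autosomal totals are
## exactly 2881 Mb and 35.9 Morgans, the genome conditions all downstream
## expectations (segment counts, F_ROH denominators) are stated under.
.HG_PHYS_MB <- c(249.25, 243.20, 198.02, 191.15, 180.92, 171.12, 159.14,
                 146.36, 141.21, 135.53, 135.01, 133.85, 115.17, 107.35,
                 102.53,  90.35,  81.20,  78.08,  59.13,  63.03,  48.13,
                  51.30)
.HG_GEN_CM  <- c(286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0,
                 166.4, 181.1, 158.2, 174.7, 125.9, 120.2, 141.9, 134.0,
                 128.5, 117.9, 107.9, 108.3,  62.8,  74.1)
.AUTOSOME_MB <- 2881
.AUTOSOME_MORGANS <- 35.9
.X_PHYS_MB <- 155.27
.X_GEN_CM  <- 180

#' Construct a synthetic genetic map
#'
#' Builds a piecewise-constant recombination map on ~1 Mb tiles. Local rates
#' are Gamma-distributed multipliers (mean 1, coefficient of variation equal
#' to `heterogeneity`) applied to each chromosome's average rate, then
#' normalized so the per-chromosome genetic lengths are matched exactly.
#' `heterogeneity = 0` yields a uniform rate. Defaults approximate the human
#' autosomes: 22 chromosomes totalling 2881 Mb and 35.9 Morgans.
#'
#' @param nChrom number of chromosomes.
#' @param physicalLengthsBp physical chromosome lengths in bp.
#' @param geneticLengthsCm genetic chromosome lengths in cM.
#' @param heterogeneity coefficient of variation of local recombination
#'   rates; 0 gives a constant rate per chromosome.
#' @param tileBp tile width in bp over which the rate is constant.
#' @param rateBlockMb spatial correlation scale of rate variation: one
#'   Gamma multiplier is drawn per block of this many Mb and applied to
#'   all tiles in the block, mimicking the broad regional (arm-scale)
#'   rate variation of real maps. Set to `tileBp / 1e6` for independent
#'   tile rates.
#' @param includeX append an X chromosome (155.27 Mb, 180 cM female map)?
#'   The X is excluded from all autosomal quantities.
#' @param seed integer seed for the tile rate draws.
#' @return a [GeneticMap-class].
#' @examples
#' map <- makeGeneticMap(seed = 1)
#' totalMorgans(map)     # ~35.9
#' physicalLengthMb(map) # 2881
#' @export
makeGeneticMap <- function(nChrom = 22,
                           physicalLengthsBp = NULL,
                           geneticLengthsCm = NULL,
                           heterogeneity = 1,
                           tileBp = 1e6,
                           rateBlockMb = 30,
                           includeX = FALSE,
                           seed = NULL) {
  if (is.null(physicalLengthsBp)) {
    if (nChrom == 22) {
      physicalLengthsBp <- .HG_PHYS_MB / sum(.HG_PHYS_MB) * .AUTOSOME_MB * 1e6
    } else {
      physicalLengthsBp <- rep(.AUTOSOME_MB * 1e6 / nChrom, nChrom)
    }
  }
  if (is.null(geneticLengthsCm)) {
    if (nChrom == 22) {
      geneticLengthsCm <- .HG_GEN_CM / sum(.HG_GEN_CM) * .AUTOSOME_MORGANS * 100
    } else {
      geneticLengthsCm <- rep(.AUTOSOME_MORGANS * 100 / nChrom, nChrom)
    }
  }
  if (length(physicalLengthsBp) != nChrom || length(geneticLengthsCm) != nChrom)
    stop("length of physicalLengthsBp / geneticLengthsCm must equal nChrom")
  if (any(physicalLengthsBp <= 0) || any(geneticLengthsCm <= 0))
    stop("chromosome lengths must be positive")
  if (heterogeneity < 0) stop("heterogeneity must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  chromNames <- as.character(seq_len(nChrom))
  lengthsBp <- physicalLengthsBp
  geneticCm <- geneticLengthsCm
  if (includeX) {
    chromNames <- c(chromNames, "X")
    lengthsBp <- c(lengthsBp, .X_PHYS_MB * 1e6)
    geneticCm <- c(geneticCm, .X_GEN_CM)
  }

  anchorsBp <- vector("list", length(chromNames))
  anchorsCm <- vector("list", length(chromNames))
  for (i in seq_along(chromNames)) {
    L <- lengthsBp[i]
    b <- unique(c(seq(0, L, by = tileBp), L))
    w <- diff(b)
    if (heterogeneity == 0) {
      mult <- rep(1, length(w))
    } else {
      shp <- 1 / heterogeneity^2
      blk <- findInterval(b[-length(b)], seq(0, L, by = rateBlockMb * 1e6))
      blockMult <- pmax(rgamma(max(blk), shape = shp, rate = shp), 1e-8)
      mult <- blockMult[blk]
    }
    cm <- cumsum(w * mult)
    cm <- cm / cm[length(cm)] * geneticCm[i]
    anchorsBp[[i]] <- b
    anchorsCm[[i]] <- c(0, cm)
  }
  new("GeneticMap", chromNames = chromNames, lengthsBp = lengthsBp,
      anchorsBp = anchorsBp, anchorsCm = anchorsCm)
}

#' Total genetic length of a map in Morgans
#'
#' @param map a [GeneticMap-class].
#' @param autosomesOnly drop the X chromosome if present?
#' @return numeric(1), Morgans.
#' @export
totalMorgans <- function(map, autosomesOnly = TRUE) {
  keep <- .autosomeIdx(map, autosomesOnly)
  sum(vapply(map@anchorsCm[keep], function(x) x[length(x)], 0)) / 100
}

#' Total physical length of a map in Mb
#'
#' @inheritParams totalMorgans
#' @return numeric(1), Mb.
#' @export
physicalLengthMb <- function(map, autosomesOnly = TRUE) {
  sum(map@lengthsBp[.autosomeIdx(map, autosomesOnly)]) / 1e6
}

#' Chromosome names of a map
#' @param map a [GeneticMap-class].
#' @return character vector.
#' @export
chromNames <- function(map) map@chromNames

.autosomeIdx <- function(map, autosomesOnly = TRUE) {
  if (autosomesOnly) which(map@chromNames != "X") else seq_along(map@chromNames)
}

#' Interpolate genetic position from physical position
#'
#' Linear interpolation of cumulative cM at arbitrary physical positions.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name (single value, recycled) or vector.
#' @param posBp physical positions in bp.
#' @return numeric, cumulative cM.
#' @export
genPos <- function(map, chrom, posBp) {
  chrom <- rep_len(as.character(chrom), length(posBp))
  out <- numeric(length(posBp))
  for (cn in unique(chrom)) {
    i <- match(cn, map@chromNames)
    if (is.na(i)) stop("unknown chromosome: ", cn)
    sel <- chrom == cn
    out[sel] <- approx(map@anchorsBp[[i]], map@anchorsCm[[i]],
                       xout = posBp[sel], rule = 2)$y
  }
  out
}

#' Interpolate physical position from genetic position
#'
#' Inverse of [genPos()]; exact at anchors.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name (single value, recycled) or vector.
#' @param cm cumulative genetic positions in cM.
#' @return numeric, bp.
#' @export
physPos <- function(map, chrom, cm) {
  chrom <- rep_len(as.character(chrom), length(cm))
  out <- numeric(length(cm))
  for (cn in unique(chrom)) {
    i <- match(cn, map@chromNames)
    if (is.na(i)) stop("unknown chromosome: ", cn)
    sel <- chrom == cn
    out[sel] <- approx(map@anchorsCm[[i]], map@anchorsBp[[i]],
                       xout = cm[sel], rule = 2, ties = "ordered")$y
  }
  out
}

## Genome-scale interval table used by the meiosis engine. Coordinates are
## concatenated ("genome") coordinates: chromosome i occupies
## (offset[i], offset[i] + length[i]]. Only the requested chromosomes are
## included (default: autosomes).
.mapIntervals <- function(map, chroms = NULL) {
  idx <- if (is.null(chroms)) .autosomeIdx(map) else match(as.character(chroms), map@chromNames)
  lens <- map@lengthsBp[idx]
  ## chromStart[k+1] must be the *identical* double as chromEnd[k]: both
  ## come from one cumulative vector (cumsum's long-double accumulation
  ## would otherwise put phase-switch positions 1 ulp off the chromosome
  ## boundary and shred segments there).
  cs <- cumsum(lens)
  offs <- c(0, cs[-length(cs)])
  ends <- cs
  start <- numeric(0); width <- numeric(0); dM <- numeric(0)
  for (k in seq_along(idx)) {
    i <- idx[k]
    b <- map@anchorsBp[[i]]
    cm <- map@anchorsCm[[i]]
    nb <- length(b)
    ts <- offs[k] + b[-nb]
    te <- offs[k] + b[-1]
    te[nb - 1L] <- ends[k]   # last tile ends exactly at the chromosome end
    start <- c(start, ts)
    width <- c(width, te - ts)
    dM <- c(dM, diff(cm) / 100)
  }
  list(start = start, width = width, dM = dM, pB = pmin(1, dM),
       chromNames = map@chromNames[idx],
       chromStart = offs, chromEnd = ends,
       totalBp = ends[length(ends)])
}

#' Write a genetic map as per-chromosome text files
#'
#' One file per chromosome named `chr<ID>.map`, three columns:
#' `pos_bp` (anchor position), `rate_cM_Mb` (constant rate of the interval
#' starting at the anchor; 0 on the last row) and `cum_cM`.
#'
#' @param map a [GeneticMap-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the file paths written.
#' @export
writeGeneticMap <- function(map, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(map@chromNames))
  for (i in seq_along(map@chromNames)) {
    b <- map@anchorsBp[[i]]
    cm <- map@anchorsCm[[i]]
    rate <- c(diff(cm) / (diff(b) / 1e6), 0)
    df <- data.frame(pos_bp = b, rate_cM_Mb = rate, cum_cM = cm)
    paths[i] <- file.path(dir, paste0("chr", map@chromNames[i], ".map"))
    write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a genetic map written by [writeGeneticMap()]
#'
#' @param dir directory holding `chr*.map` files.
#' @return a [GeneticMap-class].
#' @export
readGeneticMap <- function(dir) {
  files <- list.files(dir, pattern = "^chr.*\\.map$", full.names = TRUE)
  if (!length(files)) stop("no chr*.map files in ", dir)
  ids <- sub("\\.map$", "", sub("^chr", "", basename(files)))
  num <- suppressWarnings(as.numeric(ids))
  ord <- order(is.na(num), num, ids)  # numeric chromosomes first, then X
  files <- files[ord]; ids <- ids[ord]
  anchorsBp <- list(); anchorsCm <- list(); lens <- numeric(0)
  for (k in seq_along(files)) {
    df <- read.table(files[k], header = TRUE, sep = "\t")
    anchorsBp[[k]] <- df$pos_bp
    anchorsCm[[k]] <- df$cum_cM
    lens[k] <- df$pos_bp[nrow(df)]
  }
  new("GeneticMap", chromNames = ids, lengthsBp = lens,
      anchorsBp = anchorsBp, anchorsCm = anchorsCm)
}
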