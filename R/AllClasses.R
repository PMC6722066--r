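#' @import methods
#' @importFrom stats approx optimize pnorm qnorm rbinom rpois runif rnorm
#'   rgamma rexp lm glm quasipoisson coef vcov dnorm median sd var
#'   complete.cases model.matrix setNames quantile rnbinom binom.test
#' @importFrom utils head tail read.table write.table
NULL

## Central S4 containers. Segments (ROH / true-HBD intervals) are plain
## GRanges with metadata columns `kind`, `lengthMb` and (for ROH) `nSnps`,
## so the usual range algebra applies to them directly.

#' GeneticMap: piecewise-linear physical-to-genetic map
#'
#' A per-chromosome map from physical position (bp) to cumulative genetic
#' position (cM), stored as anchor vectors. Local recombination rates are
#' piecewise constant between anchors. Chromosome coordinates are 1-based;
#' anchors start at position 0 with 0 cM and end at the chromosome's physical
#' length.
#'
#' @slot chromNames character, chromosome identifiers (e.g. "1".."22", "X").
#' @slot lengthsBp numeric, physical length of each chromosome in bp.
#' @slot anchorsBp list of numeric vectors, anchor positions per chromosome
#'   (each starts at 0 and ends at the chromosome length).
#' @slot anchorsCm list of numeric vectors, cumulative cM at each anchor
#'   (first element 0, non-decreasing).
#'
#' @seealso [makeGeneticMap()], [totalMorgans()], [genPos()]
#' @export
setClass("GeneticMap",
  representation(
    chromNames = "character",
    lengthsBp  = "numeric",
    anchorsBp  = "list",
    anchorsCm  = "list"
  )
)

setValidity("GeneticMap", function(object) {
  n <- length(object@chromNames)
  if (length(object@lengthsBp) != n || length(object@anchorsBp) != n ||
      length(object@anchorsCm) != n)
    return("chromNames, lengthsBp, anchorsBp and anchorsCm must have equal length")
  if (any(object@lengthsBp <= 0))
    return("chromosome physical lengths must be positive")
  for (i in seq_len(n)) {
    bp <- object@anchorsBp[[i]]
    cm <- object@anchorsCm[[i]]
    if (length(bp) != length(cm))
      return("anchor position and cM vectors must align")
    if (bp[1] != 0 || cm[1] != 0)
      return("first anchor must be (0 bp, 0 cM)")
    if (is.unsorted(bp, strictly = TRUE))
      return("anchor positions must be strictly increasing")
    if (is.unsorted(cm))
      return("cumulative cM must be non-decreasing")
    if (abs(bp[length(bp)] - object@lengthsBp[i]) > 0.5)
      return("last anchor must sit at the chromosome's physical length")
  }
  TRUE
})

#' SnpPanel: genotyping panel over a GeneticMap
#'
#' Sorted SNP positions with population allele frequencies, one set per
#' chromosome of the underlying map. Frequencies refer to the counted
#' (dosage) allele; the minor allele frequency is bounded below by the
#' panel's MAF floor.
#'
#' @slot map a [GeneticMap-class].
#' @slot chromIdx integer, chromosome index (into the map) of each SNP.
#' @slot posBp numeric, 1-based physical position of each SNP.
#' @slot freq numeric, counted-allele frequency of each SNP.
#' @slot mafFloor numeric(1), the MAF filter applied at construction.
#'
#' @seealso [makeSnpPanel()]
#' @export
setClass("SnpPanel",
  representation(
    map      = "GeneticMap",
    chromIdx = "integer",
    posBp    = "numeric",
    freq     = "numeric",
    mafFloor = "numeric"
  )
)

setValidity("SnpPanel", function(object) {
  if (length(object@chromIdx) != length(object@posBp) ||
      length(object@posBp) != length(object@freq))
    return("chromIdx, posBp and freq must align")
  if (any(object@freq < object@mafFloor - 1e-12) ||
      any(object@freq > 1 - object@mafFloor + 1e-12))
    return("allele frequencies violate the MAF floor")
  if (is.unsorted(object@chromIdx))
    return("SNPs must be ordered by chromosome")
  for (ci in unique(object@chromIdx)) {
    p <- object@posBp[object@chromIdx == ci]
    if (is.unsorted(p, strictly = TRUE))
      return("SNP positions must be strictly increasing within chromosomes")
  }
  TRUE
})

#' FounderPanel: founder haplotypes over a SnpPanel
#'
#' `2N` founder haplotypes stored column-wise as a raw 0/1 matrix. Each
#' haplotype carries a unique integer label (its column index); pedigree
#' simulation tracks these labels to extract true homozygosity-by-descent.
#' With `background = "off"` alleles at distinct sites are independent draws
#' from the panel frequencies; with `background = "calibrated"` founder
#' haplotypes are mosaics of a small ancestral haplotype pool, so nominally
#' unrelated founders share long tracts (see [makeFounders()]).
#'
#' @slot panel a [SnpPanel-class].
#' @slot haplo raw matrix, nSnps x 2N, 0/1 alleles.
#' @slot background character(1), "off" or "calibrated".
#' @slot calibration list, calibration metadata (ancestral pool size,
#'   generation depth, seed) when background is "calibrated".
#'
#' @export
setClass("FounderPanel",
  representation(
    panel       = "SnpPanel",
    haplo       = "matrix",
    background  = "character",
    calibration = "list"
  )
)

setValidity("FounderPanel", function(object) {
  if (!is.raw(object@haplo))
    return("haplo must be a raw matrix")
  if (nrow(object@haplo) != length(object@panel@posBp))
    return("haplotype rows must match the SNP panel")
  if (ncol(object@haplo) %% 2 != 0)
    return("founders carry two haplotypes each")
  if (!object@background %in% c("off", "calibrated"))
    return("background must be 'off' or 'calibrated'")
  TRUE
})

#' OriginGenome: a diploid genome with founder-origin labels
#'
#' A simulated individual represented as two haplotype tilings (half-open
#' intervals in concatenated genome coordinates, each carrying the label of
#' the founder haplotype it descends from) plus, optionally, per-SNP
#' genotypes (0/1/2 dosage, NA missing) aligned to a SnpPanel.
#'
#' @slot map a [GeneticMap-class].
#' @slot tiling1,tiling2 lists with elements `e` (numeric segment end
#'   coordinates, genome scale) and `l` (integer founder-haplotype labels).
#' @slot genotypes integer, per-SNP dosage or NA; length 0 when genotypes
#'   were not materialized.
#' @slot matingType character(1), pedigree code this genome was drawn from.
#'
#' @export
setClass("OriginGenome",
  representation(
    map        = "GeneticMap",
    tiling1    = "list",
    tiling2    = "list",
    genotypes  = "integer",
    matingType = "character"
  )
)

setValidity("OriginGenome", function(object) {
  for (t in list(object@tiling1, object@tiling2)) {
    if (!all(c("e", "l") %in% names(t)))
      return("tilings need elements 'e' and 'l'")
    if (length(t$e) != length(t$l))
      return("tiling ends and labels must align")
    if (is.unsorted(t$e, strictly = TRUE))
      return("tiling ends must be strictly increasing")
  }
  TRUE
})

#' ExpMixtureModel: mixture of shifted exponential distributions
#'
#' A K-component mixture fitted to segment lengths minus a fixed shift
#' (the ROH detection threshold, 1.5 Mb by default). Components are stored
#' in decreasing-mean order, i.e. increasing rate.
#'
#' @slot K integer(1), number of components.
#' @slot weights numeric, mixture proportions (positive, sum 1).
#' @slot rates numeric, exponential rates in 1/Mb.
#' @slot shift numeric(1), length shift in Mb.
#' @slot logLik numeric(1), maximized log-likelihood.
#' @slot bic numeric(1), -2 logL + (2K - 1) log n.
#' @slot n integer(1), number of lengths fitted.
#' @slot converged logical(1).
#' @slot flags character, diagnostic flags ("collapsed", "nonidentifiable",
#'   "maxiter").
#'
#' @seealso [fitExpMixture()], [selectExpMixtureK()], [dExpMixture()]
#' @export
setClass("ExpMixtureModel",
  representation(
    K         = "integer",
    weights   = "numeric",
    rates     = "numeric",
    shift     = "numeric",
    logLik    = "numeric",
    bic       = "numeric",
    n         = "integer",
    converged = "logical",
    flags     = "character"
  )
)

setValidity("ExpMixtureModel", function(object) {
  if (length(object@weights) != object@K || length(object@rates) != object@K)
    return("weights and rates must have length K")
  if (any(object@weights <= 0) || abs(sum(object@weights) - 1) > 1e-6)
    return("weights must be positive and sum to 1")
  if (any(object@rates <= 0))
    return("rates must be positive")
  if (object@K > 1 && is.unsorted(object@rates))
    return("components must be ordered by decreasing mean (increasing rate)")
  TRUE
})

#' @describeIn GeneticMap-class compact display
#' @param object a GeneticMap
#' @export
setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d chromosome(s), %.1f Mb, %.2f Morgans\n",
              length(object@chromNames),
              sum(object@lengthsBp) / 1e6,
              totalMorgans(object)))
})

#' @describeIn SnpPanel-class compact display
#' @param object a SnpPanel
#' @export
setMethod("show", "SnpPanel", function(object) {
  cat(sprintf("SnpPanel: %d SNPs on %d chromosome(s), MAF floor %.2f\n",
              length(object@posBp),
              length(unique(object@chromIdx)),
              object@mafFloor))
})

#' @describeIn FounderPanel-class compact display
#' @param object a FounderPanel
#' @export
setMethod("show", "FounderPanel", function(object) {
  cat(sprintf("FounderPanel: %d founders (%d haplotypes), background=%s\n",
              ncol(object@haplo) / 2, ncol(object@haplo), object@background))
})

#' @describeIn OriginGenome-class compact display
#' @param object an OriginGenome
#' @export
setMethod("show", "OriginGenome", function(object) {
  cat(sprintf("OriginGenome (%s): %d + %d origin segments, %s genotypes\n",
              object@matingType,
              length(object@tiling1$e), length(object@tiling2$e),
              if (length(object@genotypes)) "with" else "no"))
})

#' @describeIn ExpMixtureModel-class compact display
#' @param object an ExpMixtureModel
#' @export
setMethod("show", "ExpMixtureModel", function(object) {
  cat(sprintf("ExpMixtureModel: K=%d, shift=%.2f Mb, logL=%.2f, BIC=%.2f\n",
              object@K, object@shift, object@logLik, object@bic))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
  cat("  rates (1/Mb):", paste(sprintf("%.3f", object@rates), collapse = " "), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
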