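#' Construct an exponential mixture model directly from parameters
#'
#' Convenience constructor used mainly for reference densities whose
#' parameters are known constants rather than fitted.
#'
#' @param weights mixture proportions (positive, sum 1).
#' @param rates exponential rates in 1/Mb.
#' @param shift length shift in Mb.
#' @return an [ExpMixtureModel-class] with NA likelihood/BIC.
#' @export
expMixtureModel <- function(weights, rates, shift = 1.5) {
  ord <- order(rates)
  new("ExpMixtureModel", K = length(weights),
      weights = weights[ord] / sum(weights), rates = rates[ord],
      shift = shift, logLik = NA_real_, bic = NA_real_, n = 0L,
      converged = NA, flags = character(0))
}

## Frozen reference constants: 2-component mixtures fitted to large
## simulated-ROH length collections under PO and FS mating (weights pi1,
## rates lambda1, lambda2 in 1/Mb on lengths minus 1.5 Mb).
.REF_PO <- list(weights = c(0.88, 0.12), rates = c(0.055, 1.309))
.REF_FS <- list(weights = c(0.87, 0.13), rates = c(0.066, 1.015))

#' Reference ROH length densities under PO and FS mating
#'
#' The pair of densities (f_PO, f_FS) the PO-vs-FS deconvolution
#' conditions on. By default these are frozen two-component exponential
#' mixture constants estimated from large ROH simulations under each
#' mating type; [fitReferenceDensities()] re-fits them from this package's
#' own simulations instead.
#'
#' @param shift length shift in Mb.
#' @return list of class `ReferenceDensities` with elements `fPO`, `fFS`
#'   (each an [ExpMixtureModel-class]) and `provenance`.
#' @export
referenceDensities <- function(shift = 1.5) {
  out <- list(fPO = expMixtureModel(.REF_PO$weights, .REF_PO$rates, shift),
              fFS = expMixtureModel(.REF_FS$weights, .REF_FS$rates, shift),
              provenance = "frozen-constants")
  class(out) <- c("ReferenceDensities", "list")
  out
}

#' @rdname referenceDensities
#' @param lengthsPO,lengthsFS ROH lengths (Mb) from simulated PO / FS
#'   offspring.
#' @param ... passed to [fitExpMixture()].
#' @export
fitReferenceDensities <- function(lengthsPO, lengthsFS, shift = 1.5, ...) {
  out <- list(fPO = fitExpMixture(lengthsPO, K = 2, shift = shift, ...),
              fFS = fitExpMixture(lengthsFS, K = 2, shift = shift, ...),
              provenance = "fitted-from-simulation")
  class(out) <- c("ReferenceDensities", "list")
  out
}

#' Log-likelihood of the PO/FS mixture proportion
#'
#' Sum over segments of log[pi f_PO(x) + (1 - pi) f_FS(x)].
#'
#' @param lengthsMb autosomal ROH lengths in Mb (all above the shift).
#' @param pi mixture proportion of PO segments, in [0, 1].
#' @param refs a [referenceDensities()] pair.
#' @return numeric(1).
#' @export
piLogLik <- function(lengthsMb, pi, refs) {
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  dpo <- dExpMixture(lengthsMb, refs$fPO)
  dfs <- dExpMixture(lengthsMb, refs$fFS)
  d <- pi * dpo + (1 - pi) * dfs
  if (any(d <= 0))
    warning("zero mixture density for some segment lengths (below shift?)")
  sum(log(d))
}

#' Maximum-likelihood PO-vs-FS deconvolution of ROH lengths
#'
#' Estimates the proportion pi of ROH segments attributable to
#' parent-offspring rather than full-sib mating by maximizing the mixture
#' log-likelihood over [0, 1] (bounded univariate optimization). The
#' standard error is the asymptotic one from the Fisher information of
#' the one-parameter mixture, with the expectation approximated by Monte
#' Carlo draws from the fitted mixture (plug-in pi-hat).
#'
#' @param lengthsMb autosomal ROH lengths in Mb (>= 2 segments).
#' @param refs a [referenceDensities()] pair.
#' @param level confidence level.
#' @param mcDraws Monte Carlo draws for the Fisher-information
#'   expectation.
#' @param seed optional integer seed for the Monte Carlo step.
#' @return list of class `DeconvolutionResult`: `pi`, `se`, `lower`,
#'   `upper`, `n`, `logLik`.
#' @export
estimatePi <- function(lengthsMb, refs, level = 0.95, mcDraws = 1e6,
                       seed = NULL) {
  if (length(lengthsMb) < 2) stop("need at least 2 segments")
  if (isTRUE(all.equal(refs$fPO@weights, refs$fFS@weights)) &&
      isTRUE(all.equal(refs$fPO@rates, refs$fFS@rates)))
    stop("reference densities are identical: pi is not identifiable")
  if (!is.null(seed)) set.seed(seed)
  opt <- optimize(function(p) piLogLik(lengthsMb, p, refs),
                  interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  piHat <- opt$maximum
  ## Fisher information under the fitted mixture, Monte Carlo expectation
  nPO <- rbinom(1, mcDraws, piHat)
  x <- c(rExpMixture(nPO, refs$fPO), rExpMixture(mcDraws - nPO, refs$fFS))
  dpo <- dExpMixture(x, refs$fPO)
  dfs <- dExpMixture(x, refs$fFS)
  info <- mean(((dpo - dfs) / (piHat * (dpo - dfs) + dfs))^2)
  se <- sqrt(1 / (length(lengthsMb) * info))
  z <- qnorm(1 - (1 - level) / 2)
  out <- list(pi = piHat, se = se,
              lower = max(0, piHat - z * se),
              upper = min(1, piHat + z * se),
              level = level, n = length(lengthsMb), logLik = opt$objective)
  class(out) <- c("DeconvolutionResult", "list")
  out
}

#' Assign individuals to PO-like or FS-like groups
#'
#' Each individual is assigned by comparing the total log-likelihood of
#' its autosomal ROH lengths under the PO reference density versus the FS
#' reference density: Group2 (PO-like) when the PO likelihood is larger,
#' Group1 (FS-like) when smaller, NA on exact ties.
#'
#' @param segmentLengths list of numeric vectors, one per individual
#'   (autosomal ROH lengths in Mb, each individual non-empty).
#' @param refs a [referenceDensities()] pair.
#' @return character vector ("Group1"/"Group2"/NA) of the same length.
#' @export
assignMatingGroups <- function(segmentLengths, refs) {
  vapply(segmentLengths, function(x) {
    if (!length(x)) stop("each individual needs at least one segment")
    dpo <- sum(dExpMixture(x, refs$fPO, log = TRUE))
    dfs <- sum(dExpMixture(x, refs$fFS, log = TRUE))
    if (dpo > dfs) "Group2" else if (dpo < dfs) "Group1" else NA_character_
  }, "")
}
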