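## X-chromosome consistency check. Only female meioses recombine the X
## (fathers and brothers transmit their single X intact), so F_ROH-X of a
## daughter of a father-daughter (PO) mating has expectation 0.5, versus
## 0.25 for a daughter of a brother-sister (FS) mating. These segment-level
## simulations track founder X haplotype labels only.

#' Simulate F_ROH-X of female offspring of PO or FS mating
#'
#' PO is modelled as father x daughter (the mating with a female
#' offspring), FS as brother x sister. The X genetic map is a single
#' 155.27 Mb chromosome of 180 cM (female map); paternal X transmission is
#' recombination-free.
#'
#' @param type "PO" or "FS".
#' @param n number of simulated females.
#' @param heterogeneity map rate heterogeneity (see [makeGeneticMap()]).
#' @param seed optional integer seed.
#' @return numeric vector of true X HBD fractions (the segment-level
#'   analogue of F_ROH-X).
#' @examples
#' mean(simulateXFroh("PO", 200, seed = 1))  # ~0.5
#' @export
simulateXFroh <- function(type = c("PO", "FS"), n, heterogeneity = 1,
                          seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  xmap <- makeGeneticMap(nChrom = 1, physicalLengthsBp = .X_PHYS_MB * 1e6,
                         geneticLengthsCm = .X_GEN_CM,
                         heterogeneity = heterogeneity)
  mi <- .mapIntervals(xmap, chroms = "1")
  intact <- function(lab) .founderTiling(mi, lab)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (type == "PO") {
      ## mother's X pair: labels 1,2; father's X: label 3
      daughterMat <- .meiose(intact(1L), intact(2L), mi)  # from mother
      daughterPat <- intact(3L)                            # father's X
      ## father x daughter: child X1 = father's X, X2 = daughter's gamete
      childX2 <- .meiose(daughterMat, daughterPat, mi)
      iv <- .hbdIntervals(intact(3L), childX2, mi)
    } else {
      brotherX <- .meiose(intact(1L), intact(2L), mi)      # from mother
      sisterMat <- .meiose(intact(1L), intact(2L), mi)
      sisterPat <- intact(3L)
      childX2 <- .meiose(sisterMat, sisterPat, mi)
      iv <- .hbdIntervals(brotherX, childX2, mi)
    }
    out[i] <- sum(iv$end - iv$start) / mi$totalBp
  }
  out
}
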