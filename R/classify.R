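#' Rank-based ROC curve and AUC
#'
#' AUC by the Mann-Whitney rank formulation (ties contribute 1/2), together
#' with the empirical ROC curve over all score thresholds (classification
#' rule: score > threshold) and the Youden-optimal operating point
#' (maximizing sensitivity + specificity - 1).
#'
#' @param scores numeric classifier scores.
#' @param labels logical or 0/1; TRUE/1 marks the positive class.
#' @return a list of class `RocResult`: `auc`, `curve` (data.frame with
#'   `threshold`, `sensitivity`, `specificity`), `optimalThreshold`,
#'   `sensAtOpt`, `specAtOpt`, `n1`, `n0`.
#' @examples
#' rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  u <- sort(unique(scores))
  thr <- c(-Inf, u)
  ## cumulative class counts at scores <= u[j]
  nle1 <- cumsum(tabulate(findInterval(scores[labels], u), nbins = length(u)))
  nle0 <- cumsum(tabulate(findInterval(scores[!labels], u), nbins = length(u)))
  sens <- c(n1, n1 - nle1) / n1   # cases with score > threshold
  spec <- c(0, nle0) / n0         # controls with score <= threshold
  youden <- sens + spec - 1
  opt <- which.max(youden)
  res <- list(auc = auc,
              curve = data.frame(threshold = thr, sensitivity = sens,
                                 specificity = spec),
              optimalThreshold = thr[opt],
              sensAtOpt = sens[opt], specAtOpt = spec[opt],
              n1 = n1, n0 = n0)
  class(res) <- c("RocResult", "list")
  res
}

#' Trapezoidal area under an empirical ROC curve
#'
#' Companion to [rocAuc()]; integrates the (1 - specificity, sensitivity)
#' curve by trapezoids. Equals the rank AUC on any input.
#'
#' @param roc a `RocResult`.
#' @return numeric(1).
#' @export
rocTrapezoidArea <- function(roc) {
  fpr <- 1 - roc$curve$specificity
  tpr <- roc$curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Classifier thresholds for extreme-inbreeding calls
#'
#' @param eiThreshold F_ROH above which extreme inbreeding (EI) is called
#'   (0.1, the ACMG-recommended consanguinity threshold).
#' @param mt1Threshold F_ROH above which an EI case is called MT1
#'   (first-degree parental mating) rather than MT2 (0.17).
#' @param poCountThreshold N_ROH at or below which an MT1 case is called
#'   parent-offspring rather than full-sib (41; PO produces fewer, longer
#'   ROHs).
#' @param poStrict use strict `<` instead of `<=` for the PO call.
#' @param controlThreshold F_ROH below which an individual is an EI
#'   control (0.01).
#' @return a named list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(eiThreshold = 0.1, mt1Threshold = 0.17,
                             poCountThreshold = 41, poStrict = FALSE,
                             controlThreshold = 0.01) {
  stopifnot(eiThreshold > 0, eiThreshold < 1,
            mt1Threshold > 0, mt1Threshold < 1,
            poCountThreshold > 0, controlThreshold > 0)
  cfg <- list(eiThreshold = eiThreshold, mt1Threshold = mt1Threshold,
              poCountThreshold = poCountThreshold, poStrict = poStrict,
              controlThreshold = controlThreshold)
  class(cfg) <- c("ClassifierConfig", "list")
  cfg
}

#' Threshold classification of EI status and mating type
#'
#' EI is called for F_ROH strictly above the EI threshold; EI cases with
#' F_ROH above the MT1 threshold are called MT1, the rest MT2; MT1 cases
#' with N_ROH at or below the count threshold are called PO, the rest FS.
#'
#' @param profiles data.frame with at least `fROH` and `nROH` columns (as
#'   produced by [inbreedingProfile()] or [simulateRohCohort()]).
#' @param config a [classifierConfig()].
#' @return `profiles` with added logical column `ei`, character columns
#'   `matingClassCall` ("MT1"/"MT2", NA for non-EI) and `poFsCall`
#'   ("PO"/"FS", NA outside MT1), and logical `control`.
#' @export
classifyMating <- function(profiles, config = classifierConfig()) {
  if (!all(c("fROH", "nROH") %in% names(profiles)))
    stop("profiles must contain fROH and nROH")
  f <- profiles$fROH
  ei <- f > config$eiThreshold
  cls <- ifelse(ei, ifelse(f > config$mt1Threshold, "MT1", "MT2"),
                NA_character_)
  po <- if (config$poStrict) profiles$nROH < config$poCountThreshold
        else profiles$nROH <= config$poCountThreshold
  poFs <- ifelse(!is.na(cls) & cls == "MT1",
                 ifelse(po, "PO", "FS"), NA_character_)
  profiles$ei <- ei
  profiles$matingClassCall <- cls
  profiles$poFsCall <- poFs
  profiles$control <- f < config$controlThreshold
  profiles
}

#' Prevalence with confidence interval
#'
#' Point estimate k/n with a normal-approximation (Wald) interval by
#' default, or an exact Clopper-Pearson interval. The reciprocal ("one in
#' x") forms round to the nearest integer.
#'
#' @param k number of cases.
#' @param n sample size.
#' @param level confidence level.
#' @param method "wald" or "clopper-pearson".
#' @return a list of class `PrevalenceEstimate`: `k`, `n`, `point`,
#'   `lower`, `upper` (fractions), `reciprocal` (rounded 1/point) and
#'   `reciprocalCI` = c(1/lower, 1/upper) rounded (the first element is
#'   the rarer bound).
#' @examples
#' prevalenceCI(125, 456414)
#' @export
prevalenceCI <- function(k, n, level = 0.95,
                         method = c("wald", "clopper-pearson")) {
  method <- match.arg(method)
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0")
  p <- k / n
  if (method == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lower <- max(0, p - half); upper <- min(1, p + half)
  } else {
    ci <- binom.test(k, n, conf.level = level)$conf.int
    lower <- ci[1]; upper <- ci[2]
  }
  out <- list(k = k, n = n, point = p, lower = lower, upper = upper,
              level = level, method = method,
              reciprocal = if (p > 0) round(1 / p) else NA_real_,
              reciprocalCI = c(if (lower > 0) round(1 / lower) else NA_real_,
                               if (upper > 0) round(1 / upper) else NA_real_))
  class(out) <- c("PrevalenceEstimate", "list")
  out
}

#' Upper-tail Gaussian probability
#'
#' Probability that a normal variate exceeds a threshold; used to check
#' observed mating-type misclassification rates against a normal
#' approximation of the F_ROH distribution (e.g. N(0.0625, 0.024) above
#' 0.1 for first-cousin offspring).
#'
#' @param mean,sd normal parameters (sd > 0).
#' @param threshold cut point.
#' @return numeric(1), P(X > threshold).
#' @examples
#' normalTailProb(0.0625, 0.024, 0.1)  # ~0.059
#' @export
normalTailProb <- function(mean, sd, threshold) {
  if (sd <= 0) stop("sd must be positive")
  pnorm(threshold, mean = mean, sd = sd, lower.tail = FALSE)
}
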