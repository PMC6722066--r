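## Inbreeding-depression statistics on (synthetic) phenotypes: linear
## regression of standardized traits on EI status or an inbreeding
## measure, overdispersed Poisson regression for count traits (fertility,
## disease counts), the inbreeding load B = -log(RR), extrapolated
## per-unit-F effect sizes, and the test of linearity of the depression.

## Default planted per-unit-F slopes (trait SD per unit F_ROH) for the ten
## synthetic control traits; magnitudes span the range of reported
## inbreeding-depression effects on fitness-related traits.
.DEFAULT_TRAIT_SLOPES <- c(PEF = -3.88, Height = -2.46, HGS = -2.35,
                           FIS = -3.43, MTCIM = -1.99, AA = -3.31,
                           EA = -1.67, VA = -2.21, NCh = -1.31,
                           HWR = -1.01)

#' Simulate phenotypes with planted inbreeding depression
#'
#' Generates covariates (two continuous confounders, one categorical
#' batch/centre factor, ten structure components), quantitative traits
#' declining linearly in the inbreeding coefficient, and an overdispersed
#' count trait with log-mean mu0 - B x F (gamma-Poisson, i.e. negative
#' binomial, overdispersion).
#'
#' @param profiles data.frame with column `fROH` (one row per
#'   individual), e.g. from [simulateRohCohort()], or any table of
#'   inbreeding coefficients.
#' @param traitSlopes named numeric vector of per-unit-F slopes (trait SD
#'   per unit inbreeding); one quantitative trait is generated per entry.
#' @param countB inbreeding load planted on the count trait (log-scale
#'   slope is -countB).
#' @param countMu0 baseline mean of the count trait at F = 0.
#' @param countTheta negative-binomial size (smaller = more
#'   overdispersion); Inf gives plain Poisson.
#' @param noiseSD residual SD of the quantitative traits.
#' @param nCentres levels of the categorical covariate.
#' @param seed optional integer seed.
#' @return data.frame with `id`, `fROH`, covariates (`age`, `tdi`,
#'   `centre`, `pc1`..`pc10`), one column per quantitative trait and a
#'   `count` column.
#' @export
simulatePhenotypes <- function(profiles,
                               traitSlopes = .DEFAULT_TRAIT_SLOPES,
                               countB = 1.46, countMu0 = 1.78,
                               countTheta = 5, noiseSD = 1,
                               nCentres = 5, seed = NULL) {
  if (!"fROH" %in% names(profiles)) stop("profiles must contain fROH")
  if (!all(is.finite(traitSlopes))) stop("trait slopes must be finite")
  if (countB < 0) stop("countB must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profiles)
  f <- profiles$fROH
  age <- rnorm(n)
  tdi <- rnorm(n)
  centre <- factor(sample.int(nCentres, n, replace = TRUE))
  centreEff <- rnorm(nCentres, 0, 0.2)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  out <- data.frame(id = seq_len(n), fROH = f, age = age, tdi = tdi,
                    centre = centre)
  out <- cbind(out, as.data.frame(pcs))
  covPart <- 0.1 * age - 0.1 * tdi + centreEff[as.integer(centre)]
  for (tr in names(traitSlopes))
    out[[tr]] <- covPart + traitSlopes[[tr]] * f + rnorm(n, 0, noiseSD)
  mu <- exp(log(countMu0) + 0.05 * age - countB * f)
  out$count <- if (is.infinite(countTheta)) rpois(n, mu)
               else rnbinom(n, mu = mu, size = countTheta)
  out
}

.checkFullRank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("collinear covariates: ", paste(bad, collapse = ", "))
  }
}

.regressionFrame <- function(y, predictor, covariates) {
  df <- data.frame(.y = y, .x = as.numeric(predictor))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    df <- cbind(df, covariates)
  }
  df
}

#' Linear regression of a trait on EI status or an inbreeding measure
#'
#' Ordinary least squares with covariate adjustment; reports the Wald
#' effect, standard error and p-value of the predictor. Collinear
#' covariates raise an error naming the offending columns.
#'
#' @param trait numeric response (standardized trait).
#' @param predictor EI status (0/1) or an inbreeding coefficient.
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @return list of class `RegressionResult`: `effect`, `se`, `p`, `n`,
#'   and the fitted `model`.
#' @export
fitInbreedingLm <- function(trait, predictor, covariates = NULL) {
  df <- .regressionFrame(trait, predictor, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) <= ncol(df) + 2) stop("too few observations")
  X <- model.matrix(.y ~ ., data = df)
  .checkFullRank(X)
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  out <- list(effect = sm[".x", 1], se = sm[".x", 2], p = sm[".x", 4],
              n = nrow(df), model = fit)
  class(out) <- c("RegressionResult", "list")
  out
}

#' Overdispersed Poisson regression of a count trait
#'
#' Quasi-Poisson fit with log link (IRLS); the dispersion is estimated by
#' Pearson chi-square / df and inflates the standard errors. For a binary
#' EI predictor the effect is the log relative risk; for an inbreeding
#' coefficient predictor, minus the effect is the inbreeding load B.
#'
#' @param counts non-negative integer response.
#' @param predictor EI status (0/1) or an inbreeding coefficient.
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @return list of class `RegressionResult`: `effect` (log RR), `se`,
#'   `p`, `RR`, `inbreedingLoad` (= -effect), `dispersion`, `n`,
#'   `model`.
#' @export
fitInbreedingQuasiPoisson <- function(counts, predictor, covariates = NULL) {
  if (any(counts < 0, na.rm = TRUE) ||
      any(counts != round(counts), na.rm = TRUE))
    stop("counts must be non-negative integers")
  df <- .regressionFrame(counts, predictor, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (all(df$.y == 0)) stop("degenerate fit: all counts are zero")
  X <- model.matrix(.y ~ ., data = df)
  .checkFullRank(X)
  fit <- glm(.y ~ ., data = df, family = quasipoisson(link = "log"))
  sm <- summary(fit)$coefficients
  out <- list(effect = sm[".x", 1], se = sm[".x", 2], p = sm[".x", 4],
              RR = exp(sm[".x", 1]), inbreedingLoad = -sm[".x", 1],
              dispersion = summary(fit)$dispersion, n = nrow(df),
              model = fit)
  class(out) <- c("RegressionResult", "list")
  out
}

#' Extrapolate an EI effect to a full-inbreeding scale
#'
#' Divides an estimated case-control effect by the difference in mean
#' inbreeding coefficient between cases and controls, giving trait SD per
#' unit F (the effect expected under 100% inbreeding).
#'
#' @param effect estimated effect size (trait SD).
#' @param fCases,fControls mean inbreeding coefficient in cases /
#'   controls.
#' @return numeric(1), trait SD per unit F.
#' @examples
#' extrapolateEffect(-0.656, 0.172, 0.003)  # -3.88
#' @export
extrapolateEffect <- function(effect, fCases, fControls) {
  if (fCases <= fControls)
    stop("fCases must exceed fControls (non-zero inbreeding contrast)")
  effect / (fCases - fControls)
}

#' Test deviation of EI cases from the linear depression prediction
#'
#' Compares the observed phenotypic mean of EI cases with the linear
#' prediction slope x deltaF obtained from inbreeding depression
#' estimated within controls; a Wald z combines the two standard errors.
#'
#' @param caseMean observed case mean (trait SD, relative to controls).
#' @param seCaseMean its standard error.
#' @param controlSlope per-unit-F depression slope estimated in controls.
#' @param seSlope its standard error.
#' @param deltaF difference in mean inbreeding coefficient between cases
#'   and controls.
#' @return list: `observed`, `predicted`, `z`, `p` (two-sided).
#' @export
linearityTest <- function(caseMean, seCaseMean, controlSlope, seSlope,
                          deltaF) {
  if (seCaseMean <= 0 || seSlope < 0) stop("standard errors must be positive")
  predicted <- controlSlope * deltaF
  z <- (caseMean - predicted) / sqrt(seCaseMean^2 + (deltaF * seSlope)^2)
  list(observed = caseMean, predicted = predicted, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Pre-adjust a trait: covariate residuals, inverse-normal transform,
#' outlier exclusion
#'
#' Residualizes on covariates, rank inverse-normal transforms the
#' residuals, and sets values beyond `sdLimit` standard deviations to NA.
#'
#' @param trait numeric response.
#' @param covariates data.frame of covariates (may be NULL).
#' @param sdLimit exclusion threshold in SD units.
#' @return numeric vector, transformed trait with exclusions as NA.
#' @export
preAdjustTrait <- function(trait, covariates = NULL, sdLimit = 4) {
  keep <- !is.na(trait)
  res <- rep(NA_real_, length(trait))
  if (is.null(covariates)) {
    res[keep] <- trait[keep] - mean(trait[keep])
  } else {
    df <- data.frame(.y = trait, as.data.frame(covariates))
    fit <- lm(.y ~ ., data = df, na.action = stats::na.exclude)
    res <- stats::residuals(fit)
  }
  ok <- !is.na(res)
  r <- rank(res[ok], ties.method = "average")
  z <- qnorm((r - 0.5) / sum(ok))
  z[abs(z) > sdLimit] <- NA
  res[ok] <- z
  res
}
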