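.logsumexp <- function(m) {
  ## rowwise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

.newExpMixture <- function(w, r, shift, ll, n, converged, flags) {
  ord <- order(r)  # decreasing mean = increasing rate
  new("ExpMixtureModel", K = length(w), weights = w[ord], rates = r[ord],
      shift = shift, logLik = ll, bic = -2 * ll + (2 * length(w) - 1) * log(n),
      n = as.integer(n), converged = converged, flags = flags)
}

#' Fit a mixture of shifted exponential distributions by EM
#'
#' Models segment lengths (Mb) exceeding a detection threshold `shift`:
#' because the truncated tail of an exponential is, after subtracting the
#' threshold, exponential with the same rate, lengths minus `shift` are
#' modelled as a K-component exponential mixture. K = 1 uses the
#' closed-form MLE (rate = 1/mean). For K > 1, EM is initialized by a
#' quantile split of log-lengths plus `nRestarts` random-assignment
#' restarts, keeping the best likelihood. The log-likelihood is
#' non-decreasing across EM iterations.
#'
#' @param lengthsMb segment lengths in Mb, all strictly greater than
#'   `shift`.
#' @param K number of components (>= 1).
#' @param shift length threshold in Mb (1.5 = the ROH detection minimum).
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @param nRestarts random restarts in addition to the quantile start.
#' @param minWeight smallest allowed component weight; shrinking below it
#'   flags the fit "collapsed".
#' @param seed optional integer seed for the restarts.
#' @param traceLik attach the per-iteration log-likelihood of the winning
#'   run as attribute `"logLikTrace"`.
#' @return an [ExpMixtureModel-class]; non-convergence is flagged
#'   ("maxiter"), never an error.
#' @examples
#' x <- 1.5 + rexp(500, rate = 1 / 10)
#' fitExpMixture(x, K = 1)  # rate ~0.1
#' @export
fitExpMixture <- function(lengthsMb, K, shift = 1.5, tol = 1e-8,
                          maxIter = 2000, nRestarts = 5, minWeight = 1e-4,
                          seed = NULL, traceLik = FALSE) {
  if (K < 1) stop("K must be >= 1")
  if (any(lengthsMb <= shift))
    stop("all lengths must strictly exceed the shift")
  if (!is.null(seed)) set.seed(seed)
  y <- lengthsMb - shift
  n <- length(y)
  if (K == 1) {
    r <- 1 / mean(y)
    ll <- n * log(r) - r * sum(y)
    m <- .newExpMixture(1, r, shift, ll, n, TRUE, character(0))
    if (traceLik) attr(m, "logLikTrace") <- ll
    return(m)
  }
  if (sd(y) == 0) {
    ## all lengths equal: a K>1 mixture is non-identifiable
    r <- rep(1 / mean(y), K)
    ll <- n * log(r[1]) - r[1] * sum(y)
    return(.newExpMixture(rep(1 / K, K), r, shift, ll, n, TRUE,
                          "nonidentifiable"))
  }

  runEM <- function(groups) {
    w <- as.numeric(tabulate(groups, K)) / n
    w[w == 0] <- 1 / n
    w <- w / sum(w)
    lam <- vapply(seq_len(K), function(k) {
      m <- mean(y[groups == k])
      if (!is.finite(m) || m <= 0) 1 / mean(y) else 1 / m
    }, 0)
    lam <- pmax(lam, 1e-10)
    llOld <- -Inf; flags <- character(0); conv <- FALSE
    trace <- numeric(0)
    for (it in seq_len(maxIter)) {
      ld <- outer(y, lam, function(yy, l) log(l) - l * yy) +
        rep(log(w), each = n)
      lse <- .logsumexp(ld)
      ll <- sum(lse)
      resp <- exp(ld - lse)
      w <- colMeans(resp)
      if (any(w < minWeight)) {
        flags <- unique(c(flags, "collapsed"))
        w <- pmax(w, minWeight)
      }
      w <- w / sum(w)
      lam <- colSums(resp) / pmax(colSums(resp * y), 1e-300)
      lam <- pmax(pmin(lam, 1e12), 1e-12)
      trace <- c(trace, ll)
      if (is.finite(llOld) &&
          abs(ll - llOld) <= tol * (abs(llOld) + 1e-12)) {
        conv <- TRUE
        break
      }
      llOld <- ll
    }
    if (!conv) flags <- unique(c(flags, "maxiter"))
    list(w = w, lam = lam, ll = ll, conv = conv, flags = flags,
         trace = trace)
  }

  ## quantile start on log-lengths, then random restarts
  qg <- as.integer(cut(rank(y, ties.method = "first"),
                       breaks = K, labels = FALSE))
  fits <- list(runEM(qg))
  for (s in seq_len(nRestarts))
    fits[[s + 1]] <- runEM(sample.int(K, n, replace = TRUE))
  best <- fits[[which.max(vapply(fits, function(f) f$ll, 0))]]
  m <- .newExpMixture(best$w, best$lam, shift, best$ll, n, best$conv,
                      best$flags)
  if (traceLik) attr(m, "logLikTrace") <- best$trace
  m
}

#' Select the number of mixture components by BIC
#'
#' Fits exponential mixtures with 1 to `kMax` components and selects the
#' K minimizing BIC = -2 logL + (2K - 1) log(n).
#'
#' @inheritParams fitExpMixture
#' @param kMax largest K considered.
#' @param ... passed to [fitExpMixture()].
#' @return list with elements `K` (selected), `models` (all fits) and
#'   `bic` (numeric vector).
#' @export
selectExpMixtureK <- function(lengthsMb, kMax = 10, shift = 1.5,
                              seed = NULL, ...) {
  if (length(lengthsMb) < 10) stop("need at least 10 lengths")
  if (!is.null(seed)) set.seed(seed)
  models <- lapply(seq_len(kMax), function(k)
    fitExpMixture(lengthsMb, K = k, shift = shift, ...))
  bic <- vapply(models, function(m) m@bic, 0)
  list(K = which.min(bic), models = models, bic = bic)
}

#' Density, simulation and likelihood for shifted exponential mixtures
#'
#' `dExpMixture` evaluates the mixture density on the original length
#' scale (zero at or below the shift); `rExpMixture` draws lengths from
#' the model; `logLikExpMixture` sums the log density over a length
#' vector.
#'
#' @param x lengths in Mb.
#' @param model an [ExpMixtureModel-class].
#' @param log return log density?
#' @return numeric.
#' @export
dExpMixture <- function(x, model, log = FALSE) {
  y <- x - model@shift
  d <- numeric(length(x))
  pos <- y > 0
  if (any(pos)) {
    ld <- vapply(seq_len(model@K), function(k)
      log(model@weights[k]) + log(model@rates[k]) - model@rates[k] * y[pos],
      numeric(sum(pos)))
    ld <- matrix(ld, nrow = sum(pos))
    d[pos] <- exp(.logsumexp(ld))
  }
  if (log) base::log(d) else d
}

#' @rdname dExpMixture
#' @param n number of draws.
#' @export
rExpMixture <- function(n, model) {
  comp <- sample.int(model@K, n, replace = TRUE, prob = model@weights)
  model@shift + rexp(n, rate = model@rates[comp])
}

#' @rdname dExpMixture
#' @export
logLikExpMixture <- function(x, model) sum(dExpMixture(x, model, log = TRUE))

#' Serialize / restore a mixture model as JSON
#'
#' @param model an [ExpMixtureModel-class].
#' @param path file path.
#' @return `readExpMixture` returns the model.
#' @export
writeExpMixture <- function(model, path) {
  jsonlite::write_json(
    list(K = model@K, weights = model@weights, rates = model@rates,
         shift = model@shift, logLik = model@logLik, bic = model@bic,
         n = model@n, converged = model@converged, flags = model@flags),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeExpMixture
#' @export
readExpMixture <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ExpMixtureModel", K = as.integer(j$K), weights = as.numeric(j$weights),
      rates = as.numeric(j$rates), shift = as.numeric(j$shift),
      logLik = as.numeric(j$logLik), bic = as.numeric(j$bic),
      n = as.integer(j$n), converged = as.logical(j$converged),
      flags = as.character(j$flags %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BIC of a shifted-gamma fit, for comparison
#'
#' Utility to compare the exponential-mixture fit against a (shifted)
#' gamma alternative; the gamma is fitted by direct likelihood
#' maximization. Not a supported model for inference.
#'
#' @inheritParams fitExpMixture
#' @return list with `shape`, `rate`, `logLik`, `bic`.
#' @export
gammaComparisonBIC <- function(lengthsMb, shift = 1.5) {
  if (any(lengthsMb <= shift)) stop("all lengths must exceed the shift")
  y <- lengthsMb - shift
  n <- length(y)
  nll <- function(par) -sum(stats::dgamma(y, exp(par[1]), exp(par[2]),
                                          log = TRUE))
  init <- c(log(mean(y)^2 / var(y)), log(mean(y) / var(y)))
  opt <- stats::optim(init, nll)
  list(shape = exp(opt$par[1]), rate = exp(opt$par[2]),
       logLik = -opt$value, bic = 2 * opt$value + 2 * log(n))
}
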