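## Overdispersed count-model fitting and selection.
##
## Candidate models for per-division mutation counts:
##   * single Poisson (K = 1),
##   * K-component Poisson mixtures, fitted by EM,
##   * negative binomial NB(mu, theta), fitted by profile maximum
##     likelihood (mu-hat is the sample mean for the intercept-only model;
##     theta is profiled).
## Models are compared by AIC (BIC is reported alongside) and summarized
## as Akaike weights. The fitted negative binomial maps onto an
## equivalent gamma mixing distribution over Poisson rates
## (shape = theta, scale = mu / theta), the continuous-volatility reading
## of the overdispersion.

.checkCounts <- function(counts, nMin = 1L) {
  if (!is.numeric(counts) || length(counts) < nMin)
    stop("counts must be a numeric vector of length >= ", nMin)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  as.numeric(counts)
}

#' Poisson probability mass function
#'
#' Thin validating wrapper around [stats::dpois()] (computed in log space).
#'
#' @param x non-negative integer count(s).
#' @param lambda positive Poisson rate.
#' @return `P(X = x)` for `X ~ Poisson(lambda)`.
#' @export
poissonPmf <- function(x, lambda) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  if (any(lambda <= 0)) stop("lambda must be positive")
  stats::dpois(x, lambda)
}

#' Poisson-mixture probability mass function
#'
#' `sum_k p_k * Poisson(x; lambda_k)` for mixture proportions `p` and
#' component means `lambda`.
#'
#' @param x non-negative integer count(s).
#' @param p mixture proportions summing to 1.
#' @param lambda positive component means, same length as `p`.
#' @return mixture pmf evaluated at `x`.
#' @export
poissonMixturePmf <- function(x, p, lambda) {
  if (length(p) != length(lambda))
    stop("p and lambda must have the same length")
  if (abs(sum(p) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if (any(p < 0)) stop("mixture proportions must be non-negative")
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  m <- vapply(seq_along(p), function(k) p[k] * stats::dpois(x, lambda[k]),
              numeric(length(x)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
  rowSums(m)
}

#' Negative-binomial probability mass function
#'
#' Standard NB2 parameterization with mean `mu` and shape `theta`:
#' variance `mu + mu^2/theta`. As `theta -> Inf` this reduces to
#' `Poisson(mu)`.
#'
#' @param x non-negative integer count(s).
#' @param mu positive mean.
#' @param theta positive shape (dispersion) parameter.
#' @return `P(X = x)`.
#' @export
negbinPmf <- function(x, mu, theta) {
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  stats::dnbinom(x, size = theta, mu = mu)
}

## ---------------------------------------------------------------- fits ----

#' Fitted Poisson mixture
#'
#' @slot K number of mixture components.
#' @slot p mixture proportions (sorted by component mean).
#' @slot lambda component means (ascending).
#' @slot logLik maximized observed-data log-likelihood.
#' @slot nParams `2K - 1` free parameters (K means, K - 1 free weights).
#' @slot AIC,BIC information criteria.
#' @slot converged whether EM met the relative tolerance.
#' @slot nIter EM iterations used by the best restart.
#' @export
setClass("PoissonMixtureFit",
  slots = c(K = "integer", p = "numeric", lambda = "numeric",
            logLik = "numeric", nParams = "integer",
            AIC = "numeric", BIC = "numeric",
            converged = "logical", nIter = "integer"))

setValidity("PoissonMixtureFit", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (length(object@p) != object@K || length(object@lambda) != object@K)
    msg <- c(msg, "p and lambda must have length K")
  if (abs(sum(object@p) - 1) > 1e-10) msg <- c(msg, "weights must sum to 1")
  if (any(object@lambda <= 0)) msg <- c(msg, "component means must be positive")
  if (abs(object@AIC - (2 * object@nParams - 2 * object@logLik)) > 1e-6)
    msg <- c(msg, "AIC must equal 2k - 2 logLik")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoissonMixtureFit", function(object) {
  cat(sprintf("Poisson mixture fit (K = %d)\n", object@K))
  cat("  lambda:", paste(signif(object@lambda, 5), collapse = ", "), "\n")
  cat("  p:     ", paste(signif(object@p, 4), collapse = ", "), "\n")
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f\n",
              object@logLik, object@AIC, object@BIC))
})

#' Fitted negative binomial
#'
#' @slot mu fitted mean (equals the sample mean for the intercept-only model).
#' @slot theta fitted shape parameter.
#' @slot logLik maximized log-likelihood.
#' @slot nParams 2.
#' @slot AIC,BIC information criteria.
#' @slot thetaAtBound TRUE when the shape estimate hit the upper search
#'   bound, signalling effectively Poisson (equi- or under-dispersed) data.
#' @export
setClass("NegBinFit",
  slots = c(mu = "numeric", theta = "numeric", logLik = "numeric",
            nParams = "integer", AIC = "numeric", BIC = "numeric",
            thetaAtBound = "logical"))

setMethod("show", "NegBinFit", function(object) {
  cat("Negative binomial fit\n")
  cat(sprintf("  mu %.4f  theta %.4f%s\n", object@mu, object@theta,
              if (object@thetaAtBound) " (at bound: effectively Poisson)" else ""))
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f\n",
              object@logLik, object@AIC, object@BIC))
})

#' Gamma mixing distribution equivalent to a negative binomial
#'
#' @slot shape gamma shape (equal to the negative-binomial `theta`).
#' @slot scale gamma scale (`mu / theta`, i.e. `v / mu` with `v = mu^2/theta`).
#' @slot variance implied variance of the rate distribution, `mu^2 / theta`.
#' @export
setClass("GammaParams",
  slots = c(shape = "numeric", scale = "numeric", variance = "numeric"))

setMethod("show", "GammaParams", function(object) {
  cat(sprintf("Gamma rate distribution: shape %.4f, scale %.4f (mean %.4f, var %.4f)\n",
              object@shape, object@scale, object@shape * object@scale,
              object@variance))
})

#' Dispersion summary of a count sample
#'
#' @slot n sample size.
#' @slot mean sample mean.
#' @slot variance unbiased (n - 1) sample variance.
#' @slot dhat index of dispersion, variance / mean.
#' @export
setClass("DispersionSummary",
  slots = c(n = "integer", mean = "numeric", variance = "numeric",
            dhat = "numeric"))

setMethod("show", "DispersionSummary", function(object) {
  cat(sprintf("n = %d, mean = %.4f, variance = %.4f, D-hat = %.4f\n",
              object@n, object@mean, object@variance, object@dhat))
})

## observed-data log-likelihood of a Poisson mixture
.pmLogLik <- function(x, p, lambda) {
  lc <- vapply(seq_along(p),
               function(k) log(p[k]) + stats::dpois(x, lambda[k], log = TRUE),
               numeric(length(x)))
  if (is.null(dim(lc))) lc <- matrix(lc, nrow = length(x))
  m <- apply(lc, 1L, max)
  sum(m + log(rowSums(exp(lc - m))))
}

.emOnce <- function(x, K, p, lambda, tol, maxIter) {
  llOld <- .pmLogLik(x, p, lambda)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    ## E-step: responsibilities in log space
    lc <- vapply(seq_len(K),
                 function(k) log(p[k]) + stats::dpois(x, lambda[k], log = TRUE),
                 numeric(length(x)))
    if (is.null(dim(lc))) lc <- matrix(lc, nrow = length(x))
    m <- apply(lc, 1L, max)
    denom <- m + log(rowSums(exp(lc - m)))
    r <- exp(lc - denom)
    ## M-step
    nk <- colSums(r)
    p <- nk / length(x)
    lambda <- pmax(colSums(r * x) / pmax(nk, .Machine$double.eps), 1e-12)
    ll <- .pmLogLik(x, p, lambda)
    ## EM guarantees monotone likelihood; numerical slack only
    if (ll < llOld - 1e-8 * max(1, abs(llOld)))
      stop("EM log-likelihood decreased: numerical failure")
    if (abs(ll - llOld) < tol * max(1, abs(llOld))) {
      converged <- TRUE
      llOld <- ll
      break
    }
    llOld <- ll
  }
  list(p = p, lambda = lambda, logLik = llOld, converged = converged, nIter = it)
}

#' Fit a K-component Poisson mixture by EM
#'
#' Maximum-likelihood fit via expectation-maximization with multiple
#' restarts. Component means are initialized at evenly spaced sample
#' quantiles (jittered across restarts) with uniform weights; the best
#' restart by log-likelihood is returned with components sorted by mean.
#' `K = 1` uses the closed-form Poisson MLE (the sample mean).
#'
#' @param counts non-negative integer counts, `length(counts) >= K`.
#' @param K number of components (>= 1).
#' @param nRestarts EM restarts with jittered initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations per restart.
#' @param seed optional seed for the restart jitter.
#' @return A [PoissonMixtureFit-class].
#' @export
fitPoissonMixture <- function(counts, K, nRestarts = 10L, tol = 1e-8,
                              maxIter = 500L, seed = NULL) {
  x <- .checkCounts(counts, nMin = 2L)
  if (!is.numeric(K) || K < 1 || K != floor(K)) stop("K must be an integer >= 1")
  K <- as.integer(K)
  if (length(x) < K) stop("need at least K observations")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)

  if (K == 1L) {
    lam <- mean(x)
    if (lam <= 0) lam <- 1e-12  # all-zero sample: boundary MLE
    ll <- .pmLogLik(x, 1, lam)
    best <- list(p = 1, lambda = lam, logLik = ll, converged = TRUE, nIter = 0L)
  } else {
    if (stats::var(x) == 0)
      warning("all counts identical: mixture components will coincide")
    qs <- stats::quantile(x, probs = seq(0.1, 0.9, length.out = K),
                          names = FALSE, type = 7)
    qs <- pmax(qs, 1e-3)
    best <- NULL
    for (r in seq_len(nRestarts)) {
      lam0 <- if (r == 1L) qs else qs * exp(stats::rnorm(K, 0, 0.25))
      lam0 <- pmax(lam0, 1e-3)
      fit <- .emOnce(x, K, rep(1 / K, K), lam0, tol, maxIter)
      if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
  }
  ord <- order(best$lambda)
  k <- 2L * K - 1L
  new("PoissonMixtureFit",
      K = K, p = best$p[ord], lambda = best$lambda[ord],
      logLik = best$logLik, nParams = k,
      AIC = 2 * k - 2 * best$logLik,
      BIC = k * log(n) - 2 * best$logLik,
      converged = best$converged, nIter = best$nIter)
}

#' Fit a negative binomial by profile maximum likelihood
#'
#' For the intercept-only model the MLE of `mu` is the sample mean; `theta`
#' maximizes the profile log-likelihood, searched on the log scale over
#' `[1e-3, 1e6]`. Equi- or under-dispersed samples drive `theta` to the
#' upper bound (the Poisson limit) and raise a warning.
#'
#' @param counts non-negative integer counts (n >= 2, positive variance
#'   recommended).
#' @return A [NegBinFit-class].
#' @export
fitNegbin <- function(counts) {
  x <- .checkCounts(counts, nMin = 2L)
  mu <- mean(x)
  if (mu <= 0) stop("cannot fit a negative binomial to an all-zero sample")
  nll <- function(lt) -sum(stats::dnbinom(x, size = exp(lt), mu = mu, log = TRUE))
  opt <- stats::optimize(nll, c(log(1e-3), log(1e6)))
  theta <- exp(opt$minimum)
  atBound <- theta > 1e6 * 0.5
  if (atBound)
    warning("theta at upper bound: data are not overdispersed (Poisson limit)")
  ll <- -opt$objective
  new("NegBinFit", mu = mu, theta = theta, logLik = ll, nParams = 2L,
      AIC = 4 - 2 * ll, BIC = 2 * log(length(x)) - 2 * ll,
      thetaAtBound = atBound)
}

#' Index of dispersion of a count sample
#'
#' `D-hat = s^2 / mean` with the unbiased (n - 1) sample variance; 1 for
#' Poisson data, > 1 for overdispersion.
#'
#' @param counts numeric counts, n >= 2, mean > 0.
#' @return A [DispersionSummary-class].
#' @export
indexOfDispersion <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 2L)
    stop("need at least two observations")
  m <- mean(counts)
  if (m <= 0) stop("index of dispersion undefined for mean <= 0")
  v <- stats::var(counts)
  new("DispersionSummary", n = length(counts), mean = m, variance = v,
      dhat = v / m)
}

#' Index of dispersion from reported moments
#'
#' @param mean positive mean.
#' @param sd standard deviation.
#' @return `sd^2 / mean`.
#' @examples
#' dispersionFromMoments(276, 37.7)  # 5.15
#' @export
dispersionFromMoments <- function(mean, sd) {
  if (mean <= 0) stop("mean must be positive")
  sd^2 / mean
}

#' AIC and BIC from a log-likelihood
#'
#' @param logLik maximized log-likelihood.
#' @param nParams number of free parameters.
#' @param n sample size (for BIC).
#' @return named vector `c(AIC =, BIC =)`.
#' @export
informationCriteria <- function(logLik, nParams, n) {
  c(AIC = 2 * nParams - 2 * logLik, BIC = nParams * log(n) - 2 * logLik)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`: the relative likelihood that model i is
#' the best of the candidate set.
#'
#' @param aic numeric vector of AIC values (>= 1 model).
#' @return weights summing to 1, in the input order.
#' @examples
#' akaikeWeights(c(637, 537, 511))
#' @export
akaikeWeights <- function(aic) {
  if (length(aic) < 1L || any(!is.finite(aic)))
    stop("aic must be a non-empty vector of finite values")
  rel <- exp(-(aic - min(aic)) / 2)
  rel / sum(rel)
}

#' Gamma mixing distribution of a negative binomial
#'
#' A NB(mu, theta) count arises from `Poisson(lambda)` with
#' `lambda ~ Gamma(shape = theta, scale = mu / theta)`; the scale equals
#' `v / mu` with rate variance `v = mu^2 / theta`.
#'
#' @param mu positive negative-binomial mean.
#' @param theta positive shape parameter.
#' @return A [GammaParams-class].
#' @export
nbToGamma <- function(mu, theta) {
  if (mu <= 0 || theta <= 0) stop("mu and theta must be positive")
  new("GammaParams", shape = theta, scale = mu / theta,
      variance = mu^2 / theta)
}

#' Model selection across Poisson mixtures and the negative binomial
#'
#' Fits the single Poisson, Poisson mixtures with increasing K, and the
#' negative binomial; mixtures are extended only while adding a component
#' improves AIC (larger K are dropped once AIC worsens). Akaike weights
#' are computed across all retained models; the table is sorted by AIC.
#' AIC drives the ranking, BIC is reported alongside.
#'
#' @param counts non-negative integer counts.
#' @param Kmax largest mixture size considered (default 4).
#' @param nRestarts,seed passed to [fitPoissonMixture()].
#' @return list with `table` (data.frame: model, nParams, logLik, AIC, BIC,
#'   weight) and `fits` (the fitted model objects, in table order).
#' @export
modelSelection <- function(counts, Kmax = 4L, nRestarts = 10L, seed = NULL) {
  if (Kmax < 1L) stop("Kmax must be >= 1")
  x <- .checkCounts(counts, nMin = 2L)
  if (!is.null(seed)) set.seed(seed)
  fits <- list()
  labs <- character()
  lastAIC <- Inf
  for (K in seq_len(Kmax)) {
    fit <- fitPoissonMixture(x, K, nRestarts = nRestarts)
    if (fit@AIC > lastAIC) break  # adding a component no longer improves fit
    fits[[length(fits) + 1L]] <- fit
    labs <- c(labs, if (K == 1L) "Poisson (K=1)" else sprintf("Poisson mixture (K=%d)", K))
    lastAIC <- fit@AIC
  }
  nb <- suppressWarnings(fitNegbin(x))
  fits[[length(fits) + 1L]] <- nb
  labs <- c(labs, "negative binomial")

  aic <- vapply(fits, function(f) f@AIC, numeric(1))
  tab <- data.frame(
    model = labs,
    nParams = vapply(fits, function(f) f@nParams, integer(1)),
    logLik = vapply(fits, function(f) f@logLik, numeric(1)),
    AIC = aic,
    BIC = vapply(fits, function(f) f@BIC, numeric(1)),
    weight = akaikeWeights(aic),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$AIC)
  list(table = tab[ord, , drop = FALSE], fits = fits[ord])
}
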