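## Stochastic simulators of mutator volatility and asymmetric segregation.
##
## Three families of models:
##   * pair models for mother/daughter mismatch counts in one division:
##     "replicon_variant" (Dm, Mm independent NB draws) vs
##     "division_variant" (a shared per-division gamma rate, then two
##     conditional Poisson draws);
##   * karyotype models for the mutations a cell inherits after one
##     division: "poisson_binomial" (per-chromosome-copy Poisson mismatch
##     counts at a fixed genome-wide rate, each copy's count kept or lost
##     whole by a Bernoulli(1/2) mitotic mask) and
##     "gamma_poisson_binomial" (the same with a fresh gamma-distributed
##     rate each division);
##   * a "poisson" control without a segregation step, parameterized by the
##     observed mutation rate (half the mismatch rate).
##
## Rates are per haploid genome per division; chromosome copies receive
## rate * f_i for genome fraction f_i.

.KARYO_MODELS <- c("poisson_binomial", "gamma_poisson_binomial", "poisson")
.PAIR_MODELS <- c("replicon_variant", "division_variant")

## inherited totals for nCells independent cell-divisions.
## rate: mismatch rate per haploid genome (pb/gpb) or observed mutation
## rate (poisson control, no mask).
.simulateCellTotals <- function(chromset, rate, model, theta = NULL, nCells) {
  cf <- .copyFractions(chromset)
  nc <- length(cf$fractions)
  if (model == "poisson") {
    ## no segregation step; rate is the observed rate per haploid genome
    return(stats::rpois(nCells, rate * sum(cf$fractions)))
  }
  lam <- if (model == "gamma_poisson_binomial") {
    if (is.null(theta) || theta <= 0) stop("gamma model requires theta > 0")
    stats::rgamma(nCells, shape = theta, scale = rate / theta)
  } else rep(rate, nCells)
  ## counts: nCells x nCopies; each copy kept or lost whole
  counts <- matrix(stats::rpois(nCells * nc, lambda = outer(lam, cf$fractions)),
                   nrow = nCells)
  mask <- matrix(stats::rbinom(nCells * nc, 1L, 0.5), nrow = nCells)
  rowSums(counts * mask)
}

#' Simulate one cell division on a karyotype
#'
#' Draws per-chromosome-copy mismatch counts and the Bernoulli(1/2)
#' mitotic segregation mask for a single division, returning the full
#' bookkeeping. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param chromset a [ChromosomeSet-class] (its ploidy sets copies per
#'   chromosome).
#' @param mismatchRate mismatches per haploid genome per division (for the
#'   `"poisson"` control this is interpreted as the observed mutation rate
#'   and no mask is applied).
#' @param model `"poisson_binomial"`, `"gamma_poisson_binomial"` or
#'   `"poisson"`.
#' @param theta gamma shape for the gamma model.
#' @return list with `lambdaDivision` (the genome-wide rate used),
#'   `perCopyCounts`, `chromOfCopy`, `mask` (NULL for the control) and
#'   `inheritedTotal`.
#' @export
simulateDivision <- function(chromset, mismatchRate,
                             model = c("poisson_binomial",
                                       "gamma_poisson_binomial", "poisson"),
                             theta = NULL) {
  model <- match.arg(model)
  if (mismatchRate <= 0) stop("mismatchRate must be positive")
  cf <- .copyFractions(chromset)
  if (model == "poisson") {
    tot <- stats::rpois(1L, mismatchRate * sum(cf$fractions))
    return(list(lambdaDivision = mismatchRate, perCopyCounts = NULL,
                chromOfCopy = cf$chrom, mask = NULL, inheritedTotal = tot))
  }
  lam <- if (model == "gamma_poisson_binomial") {
    if (is.null(theta) || theta <= 0) stop("gamma model requires theta > 0")
    stats::rgamma(1L, shape = theta, scale = mismatchRate / theta)
  } else mismatchRate
  counts <- stats::rpois(length(cf$fractions), lam * cf$fractions)
  mask <- stats::rbinom(length(cf$fractions), 1L, 0.5)
  list(lambdaDivision = lam, perCopyCounts = counts, chromOfCopy = cf$chrom,
       mask = mask, inheritedTotal = sum(counts * mask))
}

#' Simulate mother/daughter mismatch pairs: replicon-variant model
#'
#' Dm and Mm for each division are independent draws from
#' `NB(mu, theta)` — the rate varies within replicons, so the two cells'
#' counts are free to vary independently.
#'
#' @param mu,theta negative-binomial mean and shape.
#' @param nPairs number of divisions.
#' @param seed optional RNG seed.
#' @return data.frame with columns `Dm`, `Mm`.
#' @export
simulateRepliconVariantPairs <- function(mu, theta, nPairs, seed = NULL) {
  if (mu <= 0 || theta <= 0) stop("mu and theta must be positive")
  if (!is.null(seed)) set.seed(seed)
  data.frame(Dm = stats::rnbinom(nPairs, size = theta, mu = mu),
             Mm = stats::rnbinom(nPairs, size = theta, mu = mu))
}

#' Simulate mother/daughter mismatch pairs: division-variant model
#'
#' One genome-wide rate `lambda ~ Gamma(shape = theta, scale = mu/theta)`
#' is drawn per division; Dm and Mm are then conditionally independent
#' `Poisson(lambda)` draws, so the pair co-varies through the shared rate.
#'
#' @inheritParams simulateRepliconVariantPairs
#' @return data.frame with columns `Dm`, `Mm`, `lambda`.
#' @export
simulateDivisionVariantPairs <- function(mu, theta, nPairs, seed = NULL) {
  if (mu <= 0 || theta <= 0) stop("mu and theta must be positive")
  if (!is.null(seed)) set.seed(seed)
  lam <- stats::rgamma(nPairs, shape = theta, scale = mu / theta)
  data.frame(Dm = stats::rpois(nPairs, lam), Mm = stats::rpois(nPairs, lam),
             lambda = lam)
}

## D-hat for each column of a cohortSize x iterations matrix of counts
.dhatPerCohort <- function(m) {
  mu <- colMeans(m)
  n <- nrow(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  v / mu
}

#' Cohort dispersion of full replication-error counts
#'
#' Simulates `iterations` cohorts of `cohortSize` full counts (Dm + Mm for
#' the pair models; per-cell inherited totals for the karyotype models) and
#' returns the ensemble of per-cohort indices of dispersion.
#'
#' @param model one of `"replicon_variant"`, `"division_variant"`,
#'   `"poisson"`, `"poisson_binomial"`, `"gamma_poisson_binomial"`.
#' @param mu,theta pair-model parameters (per-side NB mean and shape); for
#'   the `"poisson"` pair control the full count is `Poisson(2 mu)`.
#' @param cohortSize divisions (cells) per cohort, >= 2.
#' @param iterations number of cohorts.
#' @param seed optional RNG seed.
#' @param chromset,rate karyotype and mismatch rate per haploid genome,
#'   required for the karyotype models.
#' @return list with `meanDhat`, `sdDhat` and the full `dhat` vector.
#' @export
cohortDispersion <- function(model, mu = NULL, theta = NULL,
                             cohortSize = 50L, iterations = 1000L,
                             seed = NULL, chromset = NULL, rate = NULL) {
  if (!model %in% c(.PAIR_MODELS, .KARYO_MODELS))
    stop("unknown model '", model, "'")
  if (cohortSize < 2L) stop("cohortSize must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  N <- cohortSize * iterations
  full <- if (model == "replicon_variant") {
    stats::rnbinom(N, size = theta, mu = mu) +
      stats::rnbinom(N, size = theta, mu = mu)
  } else if (model == "division_variant") {
    lam <- stats::rgamma(N, shape = theta, scale = mu / theta)
    stats::rpois(N, lam) + stats::rpois(N, lam)
  } else if (model == "poisson" && is.null(chromset)) {
    stats::rpois(N, 2 * mu)
  } else {
    if (is.null(chromset) || is.null(rate))
      stop("karyotype models require chromset and rate")
    .simulateCellTotals(chromset, rate, model, theta, N)
  }
  dh <- .dhatPerCohort(matrix(full, nrow = cohortSize))
  list(meanDhat = mean(dh), sdDhat = stats::sd(dh), dhat = dh)
}

#' Dispersion of inherited mutation counts on a karyotype
#'
#' Simulates cohorts of cells dividing once under a segregation model and
#' summarizes the per-cohort index of dispersion. The mismatch rate is
#' twice the observed mutation rate for the segregation models (each cell
#' inherits, on average, half of the mismatches); the `"poisson"` control
#' accumulates at the observed rate with no segregation step.
#'
#' @param chromset a [ChromosomeSet-class].
#' @param observedRate observed mutations per haploid genome per division.
#' @param model `"poisson_binomial"`, `"gamma_poisson_binomial"` or
#'   `"poisson"`.
#' @param theta gamma shape for the gamma model.
#' @param cohortSize cells per cohort.
#' @param iterations cohorts simulated.
#' @param seed optional RNG seed.
#' @return list with `meanDhat`, `sdDhat`, `dhat`.
#' @export
processDispersion <- function(chromset, observedRate,
                              model = c("poisson_binomial",
                                        "gamma_poisson_binomial", "poisson"),
                              theta = NULL, cohortSize = 200L,
                              iterations = 1000L, seed = NULL) {
  model <- match.arg(model)
  if (observedRate <= 0) stop("observedRate must be positive")
  if (!is.null(seed)) set.seed(seed)
  rate <- if (model == "poisson") observedRate else 2 * observedRate
  totals <- .simulateCellTotals(chromset, rate, model, theta,
                                cohortSize * iterations)
  dh <- .dhatPerCohort(matrix(totals, nrow = cohortSize))
  list(meanDhat = mean(dh), sdDhat = stats::sd(dh), dhat = dh)
}

#' Cumulative mutation burden over successive divisions
#'
#' Each cell accumulates independent per-division inherited totals;
#' the full trajectory matrix is returned.
#'
#' @inheritParams processDispersion
#' @param nDivisions divisions per cell (>= 1).
#' @param nCells number of independent cells.
#' @return numeric matrix `nCells x nDivisions` of cumulative burdens.
#' @export
cumulativeBurden <- function(chromset, observedRate,
                             model = c("poisson_binomial",
                                       "gamma_poisson_binomial", "poisson"),
                             theta = NULL, nDivisions = 30L, nCells = 1000L,
                             seed = NULL) {
  model <- match.arg(model)
  if (nDivisions < 1L) stop("nDivisions must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rate <- if (model == "poisson") observedRate else 2 * observedRate
  perDiv <- matrix(.simulateCellTotals(chromset, rate, model, theta,
                                       nCells * nDivisions),
                   nrow = nCells, ncol = nDivisions)
  t(apply(perDiv, 1L, cumsum))
}

#' Dispersion as a function of mutation rate
#'
#' Runs [processDispersion()] across a set of observed mutation rates.
#' Under the Poisson-binomial model the mean index of dispersion is affine
#' in the rate.
#'
#' @inheritParams processDispersion
#' @param observedRates positive rates to scan.
#' @return data.frame with columns `rate`, `meanDhat`, `sdDhat`.
#' @export
dispersionRateScan <- function(chromset, observedRates,
                               model = c("poisson_binomial",
                                         "gamma_poisson_binomial", "poisson"),
                               theta = NULL, cohortSize = 200L,
                               iterations = 1000L, seed = NULL) {
  model <- match.arg(model)
  if (any(observedRates <= 0)) stop("all rates must be positive")
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(observedRates, function(r)
    processDispersion(chromset, r, model, theta = theta,
                      cohortSize = cohortSize, iterations = iterations))
  data.frame(rate = observedRates,
             meanDhat = vapply(res, `[[`, numeric(1), "meanDhat"),
             sdDhat = vapply(res, `[[`, numeric(1), "sdDhat"))
}

#' Closed-form expected index of dispersion
#'
#' First/second-moment predictions for the simulators, from the law of
#' total variance. For a cell inheriting `T = sum_c B_c N_c` over
#' chromosome copies with `N_c ~ Poisson(R f_c)` and `B_c ~ Bernoulli(1/2)`:
#' `D = 1 + (R/2) * sum(f_c^2) / sum(f_c)`. The gamma-rate version adds
#' `R (1 + 1/theta)/2` in place of `R/2` on the quadratic term plus
#' `R sum(f_c) / (2 theta)` from between-division rate variance. The pair
#' models give `1 + mu/theta` (replicon variant) and `1 + 2 mu/theta`
#' (division variant); the Poisson control gives 1.
#'
#' @param model any simulator model name.
#' @param chromset karyotype (karyotype models only).
#' @param rate mismatch rate per haploid genome (karyotype models only).
#' @param mu,theta pair-model / gamma parameters.
#' @return the expected (large-cohort) index of dispersion.
#' @export
expectedDispersion <- function(model, chromset = NULL, rate = NULL,
                               mu = NULL, theta = NULL) {
  switch(model,
    poisson = 1,
    replicon_variant = 1 + mu / theta,
    division_variant = 1 + 2 * mu / theta,
    poisson_binomial = {
      cf <- .copyFractions(chromset)
      1 + (rate / 2) * sum(cf$fractions^2) / sum(cf$fractions)
    },
    gamma_poisson_binomial = {
      cf <- .copyFractions(chromset)
      1 + (rate * (1 + 1 / theta) / 2) * sum(cf$fractions^2) / sum(cf$fractions) +
        rate * sum(cf$fractions) / (2 * theta)
    },
    stop("unknown model '", model, "'")
  )
}
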