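# Moment oracles used throughout (law of total variance, derived before
# the simulators):
#   replicon variant: full = X + Y, X,Y iid NB(mu, theta)
#     -> D = [2(mu + mu^2/theta)] / (2 mu) = 1 + mu/theta
#   division variant: full | lam ~ Poisson(2 lam), lam ~ Gamma(theta, mu/theta)
#     -> Var = 2 mu + 4 mu^2/theta -> D = 1 + 2 mu/theta
#   poisson-binomial on copy fractions f_c at mismatch rate R:
#     T = sum_c B_c N_c, B ~ Bern(1/2), N_c ~ Pois(R f_c)
#     Var(B N) = lam/2 + lam^2/4 -> D = 1 + (R/2) sum(f_c^2) / sum(f_c)

pbOracle <- function(cs, R) {
  p <- ploidy(cs); if (length(p) == 1L) p <- rep(p, length(cs))
  fc <- rep(unname(chromFractions(cs)), times = p)
  1 + (R / 2) * sum(fc^2) / sum(fc)
}

gpbOracle <- function(cs, R, theta) {
  p <- ploidy(cs); if (length(p) == 1L) p <- rep(p, length(cs))
  fc <- rep(unname(chromFractions(cs)), times = p)
  1 + (R * (1 + 1 / theta) / 2) * sum(fc^2) / sum(fc) +
    R * sum(fc) / (2 * theta)
}

test_that("replicon-variant pairs match their moment oracle", {
  p <- simulateRepliconVariantPairs(138, 60.42, 1e5, seed = 1)
  expect_equal(mean(p$Dm), 138, tolerance = 0.01)
  expect_equal(mean(p$Mm), 138, tolerance = 0.01)
  full <- p$Dm + p$Mm
  expect_equal(var(full) / mean(full), 1 + 138 / 60.42, tolerance = 0.03)
  # no correlation between independent draws
  r2 <- summary(lm(Mm ~ Dm, data = p[1:1000, ]))$r.squared
  expect_lt(r2, 0.02)
})

test_that("division-variant pairs co-vary through the shared rate", {
  p <- simulateDivisionVariantPairs(138, 60.42, 1000, seed = 2)
  r2 <- summary(lm(Mm ~ Dm, data = p))$r.squared
  expect_equal(r2, 0.47, tolerance = 0.05 / 0.47)

  # law-of-total-variance oracle for the correlation:
  # Cov = Var(lam) = mu^2/theta; Var = mu + mu^2/theta
  big <- simulateDivisionVariantPairs(138, 60.42, 1e5, seed = 3)
  rhoOracle <- (138 / 60.42) / (1 + 138 / 60.42)
  expect_equal(cor(big$Dm, big$Mm), rhoOracle, tolerance = 0.05)

  # Poisson limit decorrelates the pair
  pl <- simulateDivisionVariantPairs(138, 1e6, 1000, seed = 4)
  expect_lt(summary(lm(Mm ~ Dm, data = pl))$r.squared, 0.02)
})

test_that("cohort dispersion reproduces the three pair-model regimes", {
  rv <- cohortDispersion("replicon_variant", 138, 60.42, 50, 1000, seed = 5)
  expect_equal(rv$meanDhat, 1 + 138 / 60.42, tolerance = 0.05)
  dv <- cohortDispersion("division_variant", 138, 60.42, 50, 1000, seed = 6)
  expect_equal(dv$meanDhat, 1 + 2 * 138 / 60.42, tolerance = 0.05)
  po <- cohortDispersion("poisson", 138, cohortSize = 50, iterations = 1000,
                         seed = 7)
  expect_equal(po$meanDhat, 1.0, tolerance = 0.05)
  expect_error(cohortDispersion("bogus", 1, 1))
})

test_that("single-division simulation has the prescribed structure", {
  y <- builtinKaryotype("yeast_s288c")
  set.seed(8)
  draws <- replicate(10000, simulateDivision(y, 69, "poisson_binomial"),
                     simplify = FALSE)
  pre <- vapply(draws, function(d) sum(d$perCopyCounts), numeric(1))
  post <- vapply(draws, function(d) d$inheritedTotal, numeric(1))
  masks <- unlist(lapply(draws, `[[`, "mask"))
  expect_equal(mean(pre), 138, tolerance = 0.02)   # diploid pre-mask total
  expect_equal(mean(post), 69, tolerance = 0.02)   # half survives the mask
  expect_equal(mean(masks), 0.5, tolerance = 3 * sqrt(0.25 / length(masks)) / 0.5)
  # conservation: inherited total is exactly the masked sum
  expect_true(all(vapply(draws, function(d)
    d$inheritedTotal == sum(d$perCopyCounts * d$mask), logical(1))))
})

test_that("toy-karyotype dispersion matches enumeration-backed oracle", {
  cs <- toyChromset(ploidy = 2L)  # fractions 0.25, 0.75, two copies each
  R <- 40
  fc <- rep(c(0.25, 0.75), each = 2)
  # brute-force check of the oracle itself on the 16 mask configurations:
  # E[T] = sum_c E[B] lam_c ; Var(T) = sum_c (lam_c/2 + lam_c^2/4)
  lam <- R * fc
  masks <- as.matrix(expand.grid(rep(list(0:1), 4)))
  # E[T|mask] = sum m_c lam_c, Var(T|mask) = sum m_c lam_c (Poisson)
  eT <- mean(masks %*% lam)
  varT <- mean(masks %*% lam) + mean((masks %*% lam)^2) - eT^2
  oracleBrute <- varT / eT
  expect_equal(oracleBrute, pbOracle(cs, R), tolerance = 1e-10)

  sim <- processDispersion(cs, R / 2, "poisson_binomial", cohortSize = 500,
                           iterations = 400, seed = 9)
  expect_equal(sim$meanDhat, pbOracle(cs, R), tolerance = 0.05)
})

test_that("one-chromosome haploid inheritance is zero-inflated Poisson", {
  cs <- ChromosomeSet("chr1", 1000L, ploidy = 1L)
  lam <- 6
  set.seed(10)
  x <- replicate(20000, simulateDivision(cs, lam, "poisson_binomial")$inheritedTotal)
  # exact law: P(0) = 1/2 + e^-lam/2; P(k) = dpois(k, lam)/2 for k >= 1
  k <- 0:20
  pk <- c(0.5 + dpois(0, lam) / 2, dpois(1:20, lam) / 2)
  obs <- table(factor(x, levels = k))
  keep <- pk * length(x) >= 5
  expect_gt(chisq.test(c(obs[keep], sum(obs[!keep])),
                       p = c(pk[keep], 1 - sum(pk[keep])))$p.value, 0.01)
})

test_that("process dispersion reproduces the yeast and human regimes", {
  y <- builtinKaryotype("yeast_s288c")
  pb <- processDispersion(y, 34.5, "poisson_binomial", cohortSize = 200,
                          iterations = 300, seed = 11)
  expect_equal(pb$meanDhat, pbOracle(y, 69), tolerance = 0.05)
  po <- processDispersion(y, 34.5, "poisson", cohortSize = 200,
                          iterations = 300, seed = 12)
  expect_equal(po$meanDhat, 1.0, tolerance = 0.05)
  gpb <- processDispersion(y, 34.5, "gamma_poisson_binomial", theta = 60.42,
                           cohortSize = 200, iterations = 300, seed = 13)
  expect_equal(gpb$meanDhat, gpbOracle(y, 69, 60.42), tolerance = 0.05)

  h <- builtinKaryotype("human_grch38")
  hp <- processDispersion(h, 950, "poisson_binomial", cohortSize = 10000,
                          iterations = 1, seed = 14)
  expect_equal(hp$meanDhat, pbOracle(h, 1900), tolerance = 0.1)
})

test_that("gamma model converges to the Poisson-binomial as theta grows", {
  y <- builtinKaryotype("yeast_s288c")
  gpb <- processDispersion(y, 34.5, "gamma_poisson_binomial", theta = 1e6,
                           cohortSize = 200, iterations = 500, seed = 15)
  pb <- processDispersion(y, 34.5, "poisson_binomial", cohortSize = 200,
                          iterations = 500, seed = 16)
  expect_equal(gpb$meanDhat, pb$meanDhat,
               tolerance = 0.02 + 3 * pb$sdDhat / sqrt(500) / pb$meanDhat)
})

test_that("identical seeds reproduce simulations bit for bit", {
  y <- builtinKaryotype("yeast_s288c")
  a <- processDispersion(y, 34.5, "poisson_binomial", cohortSize = 50,
                         iterations = 100, seed = 17)
  b <- processDispersion(y, 34.5, "poisson_binomial", cohortSize = 50,
                         iterations = 100, seed = 17)
  expect_identical(a, b)
  p1 <- simulateDivisionVariantPairs(138, 60.42, 100, seed = 18)
  p2 <- simulateDivisionVariantPairs(138, 60.42, 100, seed = 18)
  expect_identical(p1, p2)
})

test_that("cumulative burden grows linearly in mean and variance", {
  y <- builtinKaryotype("yeast_s288c")
  tr <- cumulativeBurden(y, 34.5, "poisson_binomial", nDivisions = 20,
                         nCells = 1000, seed = 19)
  d <- 20
  expect_equal(mean(tr[, d]), d * 2 * 34.5, tolerance = 0.02)

  # independent-increments oracle: across-cell variance slope ratio between
  # models equals the single-division dispersion ratio
  trP <- cumulativeBurden(y, 34.5, "poisson", nDivisions = 20,
                          nCells = 1000, seed = 20)
  ratio <- var(tr[, d]) / var(trP[, d])
  expect_equal(ratio, pbOracle(y, 69) / 1, tolerance = 0.1)

  # one division is distributed as single-division draws
  one <- cumulativeBurden(y, 34.5, "poisson_binomial", nDivisions = 1,
                          nCells = 2000, seed = 21)[, 1]
  set.seed(22)
  ref <- replicate(2000, simulateDivision(y, 69, "poisson_binomial")$inheritedTotal)
  expect_gt(suppressWarnings(ks.test(one, ref))$p.value, 0.01)
})

test_that("dispersion grows affinely with mutation rate", {
  h <- builtinKaryotype("human_grch38")
  scan <- dispersionRateScan(h, c(48, 95, 142, 190), "poisson_binomial",
                             cohortSize = 2000, iterations = 10, seed = 23)
  fit <- lm(meanDhat ~ rate, data = scan)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(scan$meanDhat[1], pbOracle(h, 96), tolerance = 0.1)
  expect_equal(scan$meanDhat[4], pbOracle(h, 380), tolerance = 0.1)
})
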