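test_that("shared callable genome is an interval intersection", {
  cs <- toyChromset()
  si <- toySeqinfo(cs)
  mk <- function(start, end) GenomicRanges::GRanges("chrA",
    IRanges::IRanges(start, end), seqinfo = si)
  keys <- list("1.D" = character())
  # identical interval sets: idempotence
  lt <- toyLineage(keys, 1, cs, callable = mk(1, 500))
  sh <- sharedCallableGenome(lt)
  expect_equal(unname(sh$lengths["chrA"]), 500)
  # overlap [0,100) and [50,150) in bed coordinates -> 50 shared bases
  lt2 <- toyLineage(keys, 1, cs,
                    callable = list("1.D" = mk(1, 100), "1.GD1" = mk(51, 150),
                                    "1.GD2" = mk(51, 150), "1.GGD" = mk(51, 150)))
  sh2 <- sharedCallableGenome(lt2, members = c("1.D", "1.GD1"))
  expect_equal(unname(sh2$lengths["chrA"]), 50)
  expect_equal(BiocGenerics::start(sh2$intervals), 51)
  expect_equal(BiocGenerics::end(sh2$intervals), 100)
  # disjoint callable sets share nothing
  lt3 <- toyLineage(keys, 1, cs,
                    callable = list("1.D" = mk(1, 100), "1.GD1" = mk(200, 300),
                                    "1.GD2" = mk(200, 300), "1.GGD" = mk(200, 300)))
  expect_equal(length(sharedCallableGenome(lt3, c("1.D", "1.GD1"))$intervals), 0L)
  expect_error(sharedCallableGenome(lt, members = character()))
  expect_error(sharedCallableGenome(lt, members = "nope"))
})

test_that("filtering keeps shared-genome multi-colony variants only", {
  cs <- toyChromset()
  si <- toySeqinfo(cs)
  cal <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 500), seqinfo = si)
  keys <- list(
    "1.D"   = c("chrA:10:T", "chrA:600:C"),  # 600 is outside callable
    "1.GD2" = c("chrA:10:T"),
    "1.GD1" = c("chrA:20:G")                  # singleton
  )
  lt <- toyLineage(keys, 1, cs, callable = cal)
  f <- filterToShared(lt)
  getKeys <- function(l, id) {
    cc <- Filter(function(x) x@colonyId == id, l@colonies)[[1]]
    v <- cc@variants
    paste(as.character(GenomeInfoDb::seqnames(v)), BiocGenerics::start(v),
          S4Vectors::mcols(v)$alt, sep = ":")
  }
  expect_equal(getKeys(f, "1.D"), "chrA:10:T")    # retained: shared + 2 colonies
  expect_equal(getKeys(f, "1.GD2"), "chrA:10:T")
  expect_equal(getKeys(f, "1.GD1"), character()) # singleton dropped
})

test_that("segregant patterns classify a hand-built pedigree", {
  spec <- data.frame(group = c("Da", "Db", "Ma", "Mb", "Da"),
                     division = c(1L, 1L, 1L, 1L, 2L))
  toy <- toyLineageWithGroups(spec, nDivisions = 5L)
  sc1 <- assignSegregantGroups(toy$lineage, 1L)
  expect_equal(unname(sc1@counts), c(1, 1, 1, 1))
  expect_equal(fullErrorCount(sc1), 4)
  expect_equal(mismatchCounts(sc1), c(Dm = 2, Mm = 2))
  expect_length(sc1@unassigned, 0L)
  sc2 <- assignSegregantGroups(toy$lineage, 2L)
  expect_equal(unname(sc2@counts), c(1, 0, 0, 0))
  # tail divisions cannot be scored (Mb needs two further daughters)
  sc3 <- assignSegregantGroups(toy$lineage, 3L)
  expect_false(sc3@scorable)
  expect_true(all(is.na(sc3@counts)))
})

test_that("count arithmetic is conserved", {
  spec <- data.frame(group = rep(c("Da", "Db", "Ma", "Mb"), c(1, 2, 3, 4)),
                     division = rep(1L, 10))
  toy <- toyLineageWithGroups(spec, nDivisions = 5L)
  sc <- assignSegregantGroups(toy$lineage, 1L)
  expect_equal(unname(sc@counts), c(1, 2, 3, 4))
  expect_equal(fullErrorCount(sc), sum(sc@counts))
  expect_equal(unname(sum(mismatchCounts(sc))), fullErrorCount(sc))
  expect_equal(colSums(sc@perChromosome), sc@counts)
})

test_that("caller round-trips the generator's ground truth exactly", {
  sim <- generateLineage(nDivisions = 12, mu = 50, theta = 60.42, seed = 101)
  res <- callLineage(sim$lineage)
  N <- nSublineages(sim$lineage)
  tr <- sim$truth[!sim$truth$noise & sim$truth$observed, ]
  for (n in seq_len(N - 3L)) {
    sc <- res$counts[[n]]
    expect_true(sc@scorable)
    truthCounts <- table(factor(tr$group[tr$division == n],
                                levels = c("Da", "Db", "Ma", "Mb")))
    expect_equal(unname(sc@counts), as.numeric(truthCounts))
    expect_length(sc@unassigned, 0L)
  }
  # conservation: every observed truth event of scorable divisions is
  # assigned to exactly its generating division
  full <- vapply(res$counts[seq_len(N - 3L)], fullErrorCount, numeric(1))
  expect_equal(sum(full), sum(tr$division <= N - 3L))
})

test_that("singleton noise does not perturb assignments", {
  clean <- generateLineage(nDivisions = 10, mu = 40, theta = 60.42, seed = 202)
  noisy <- generateLineage(nDivisions = 10, mu = 40, theta = 60.42,
                           noiseRate = 10, seed = 202)
  rc <- callLineage(clean$lineage)$summary
  rn <- callLineage(noisy$lineage)$summary
  expect_equal(rn[, c("Da", "Db", "Ma", "Mb")], rc[, c("Da", "Db", "Ma", "Mb")])
})

test_that("per-chromosome segregation classes follow all-or-none logic", {
  spec <- data.frame(group = c("Da", "Da", "Db"), division = c(1L, 1L, 1L))
  toy <- toyLineageWithGroups(spec, nDivisions = 5L)
  sc <- assignSegregantGroups(toy$lineage, 1L)
  # all three toy variants sit on chrB: fraction 2/3 -> partial
  tal <- classifySegregation(sc, "Da/Db")
  expect_equal(unname(tal@counts), c(0L, 1L, 0L))

  # forced classes from a synthetic perChromosome matrix
  sc@perChromosome[] <- 0L
  sc@perChromosome["chrA", ] <- c(5L, 0L, 0L, 0L)   # Da gets all
  sc@perChromosome["chrB", ] <- c(3L, 3L, 0L, 0L)   # even split
  sc@counts <- colSums(sc@perChromosome)
  t2 <- classifySegregation(sc, "Da/Db")
  expect_equal(unname(t2@counts), c(0L, 1L, 1L))
  expect_setequal(t2@fractions, c(1, 0.5))
})

# Exact class probabilities for the none/partial/all tally. Masks alone
# give 1:2:1, but a chromosome whose copy carries zero mutations on one
# side is forced into all/none even when the masks differ; with per-copy
# rate lam*f_i, lam ~ Gamma(theta, mean muH) shared within a division:
#   a_i = E e^(-lam f_i) = (1 + f_i muH/theta)^-theta
#   b_i = E e^(-2 lam f_i)
#   P(partial | pair total > 0) = (1 - 2 a_i + b_i) / (2 (1 - b_i))
# weighted across chromosomes by the probability 1 - b_i of being counted.
segClassOracle <- function(cs, muSide, theta) {
  f <- unname(chromFractions(cs))
  muH <- muSide / 2                     # diploid: per-haploid-genome rate
  a <- (1 + f * muH / theta)^(-theta)
  b <- (1 + 2 * f * muH / theta)^(-theta)
  pp <- sum((1 - b) * 0.5 * (1 - 2 * a + b) / (1 - b)) / sum(1 - b)
  c(none = (1 - pp) / 2, partial = pp, all = (1 - pp) / 2)
}

test_that("diploid segregation tallies are Mendelian after zero-truncation", {
  # at the study-condition rate the exact null is the truncation-corrected
  # class distribution (the published tally 876:1490:834 matches it too,
  # while deviating from a literal 1:2:1)
  pr <- segClassOracle(builtinKaryotype("yeast_s288c"), 138, 60.42)
  expect_gt(chisq.test(c(876, 1490, 834), p = pr)$p.value, 0.01)

  counts <- list()
  for (s in 1:2) {
    sim <- generateLineage(nDivisions = 28, mu = 138, theta = 60.42,
                           seed = 300 + s)
    counts <- c(counts, callLineage(sim$lineage)$counts)
  }
  tot <- classifySegregation(counts, "Da/Db")@counts +
    classifySegregation(counts, "Ma/Mb")@counts
  expect_gte(sum(tot), 1000)
  expect_gt(chisq.test(tot, p = pr)$p.value, 0.01)

  # in the high-rate regime zero-truncation vanishes and the tally is a
  # literal 1:2:1
  expect_equal(unname(segClassOracle(builtinKaryotype("yeast_s288c"),
                                     600, 60.42)),
               c(0.25, 0.5, 0.25), tolerance = 0.005)
  cnt <- list()
  for (s in 1:2) {
    sim <- generateLineage(nDivisions = 28, mu = 600, theta = 60.42,
                           seed = 700 + s)
    cnt <- c(cnt, callLineage(sim$lineage)$counts)
  }
  tot2 <- classifySegregation(cnt, "Da/Db")@counts +
    classifySegregation(cnt, "Ma/Mb")@counts
  expect_gt(chisq.test(tot2, p = c(1, 2, 1) / 4)$p.value, 0.01)
})

test_that("assignment-error signatures are detected and the blind spot is real", {
  sim <- generateLineage(nDivisions = 12, mu = 60, theta = 60.42, seed = 404)
  expect_equal(nrow(detectAssignmentErrors(sim$lineage)), 0L)

  # (a) next daughter moved in place of the first granddaughter
  corA <- injectAssignmentError(sim, 5L, "Dn1_for_GDn1")
  flagsA <- detectAssignmentErrors(corA)
  expect_true(any(flagsA$signature == "Ma_zero_recurring_Db" &
                    flagsA$division == 5L))
  # censoring monotonicity: corruption never reduces the flag count
  expect_gte(nrow(flagsA), 0L + nrow(detectAssignmentErrors(sim$lineage)))

  # (b) granddaughters swapped: putative Da variants are really Ma
  corB <- injectAssignmentError(sim, 5L, "GDn1_GDn2_swap")
  flagsB <- detectAssignmentErrors(corB)
  expect_true(any(flagsB$signature == "Da_matches_Ma" & flagsB$division == 5L))

  # (c) great-granddaughter swap: undetectable, but Db is inflated
  corC <- injectAssignmentError(sim, 5L, "GGDn1_GGDn2_swap", seed = 9)
  flagsC <- detectAssignmentErrors(corC)
  expect_equal(nrow(flagsC), 0L)
  dbClean <- callLineage(sim$lineage)$summary$Db[5]
  dbCor <- callLineage(corC)$summary$Db[5]
  expect_gt(dbCor, dbClean)

  expect_error(injectAssignmentError(sim, 5L, "bogus"))
  expect_error(injectAssignmentError(sim, 11L, "Dn1_for_GDn1"))
})

test_that("censored sublineages make dependent divisions unscorable", {
  sim <- generateLineage(nDivisions = 10, mu = 40, theta = 60.42, seed = 505)
  lt <- censorLineage(sim$lineage, 4L)
  res <- callLineage(lt)
  expect_true(all(res$summary$censored[1:4]))      # divisions 1-4 need sublineage 4
  expect_false(any(res$summary$censored[5:7]))
  expect_true(all(res$summary$censored[8:10]))     # structural tail
})
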