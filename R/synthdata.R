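## Synthetic single-cell lineages with ground truth.
##
## Generative model (division-variant gamma-Poisson with all-or-none
## strand segregation): each maternal division n draws one genome-wide
## mismatch rate lambda_n ~ Gamma(shape = theta, mean = mu). Given
## lambda_n, the mother-retained and daughter-segregated mismatch counts
## on each chromosome copy are independent Poisson(lambda_n * f_c). At
## the following division each copy's mismatch set becomes double-stranded
## and segregates whole by a Bernoulli(1/2) coin: daughter-side copies go
## to Da (retained by Dn, so shared by Dn and GDn.2) or Db (passed to
## GDn.1, shared by GDn.1 and GGDn.1); mother-side copies go to Ma
## (passed to Dn+1, present in all of sublineage n+1) or Mb (retained by
## the mother, present in every later sublineage). Once double-stranded a
## mutation is inherited by all descendants. Mutations arising within
## sublineage cells reach at most one sequenced colony and are absorbed
## into the colony-private noise channel.

.GROUPS <- c("Da", "Db", "Ma", "Mb")

## sample k distinct positions per chromosome for all events at once
.samplePositions <- function(chrom, chromset) {
  pos <- integer(length(chrom))
  lens <- chromLengths(chromset)
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    pos[i] <- sample.int(lens[[cn]], length(i))
  }
  pos
}

#' Generate a synthetic single-cell lineage with ground truth
#'
#' Simulates `nDivisions` maternal divisions of a mutator cell and emits
#' the full pedigree of colonies (four per sublineage) together with the
#' generating truth: every mismatch event's genomic position, division and
#' segregant group, and the per-division rates. Tail divisions are
#' structurally unscorable (truth rows are marked `observed = FALSE` when
#' the colonies that would reveal them were never isolated). Optional
#' colony-private singleton noise emulates sequencing errors and clonal
#' sweeps; optional per-colony callable masking exercises the
#' shared-genome intersection.
#'
#' @param nDivisions sublineages to simulate (>= 4; divisions
#'   `1..nDivisions - 3` are scorable).
#' @param mu mean mismatches per segregant side (daughter or mother) per
#'   division; the full error count has mean `2 * mu`.
#' @param theta gamma shape of the between-division rate distribution.
#' @param chromset karyotype (its ploidy sets copies per chromosome).
#' @param noiseRate expected colony-private singleton variants per colony.
#' @param maskFraction fraction of each chromosome dropped from each
#'   colony's callable intervals (a random contiguous window per
#'   chromosome per colony).
#' @param seed optional RNG seed.
#' @return list with `lineage` (a [LineageTable-class]), `truth`
#'   (data.frame: key, chrom, pos, ref, alt, division, group, observed,
#'   noise), and `lambda` (per-division gamma draws).
#' @export
generateLineage <- function(nDivisions = 53L, mu = 138, theta = 60.42,
                            chromset = builtinKaryotype("yeast_s288c"),
                            noiseRate = 0, maskFraction = 0, seed = NULL) {
  if (nDivisions < 4L) stop("nDivisions must be >= 4 to score division 1")
  if (mu <= 0 || theta <= 0) stop("mu and theta must be positive")
  if (maskFraction < 0 || maskFraction >= 0.5)
    stop("maskFraction must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(nDivisions)
  cf <- .copyFractions(chromset)
  nc <- length(cf$fractions)
  cn <- chromNames(chromset)

  ## lambda is the per-haploid-genome rate; each segregant side receives
  ## Poisson(lambda * f_c) on every chromosome copy, so the per-side mean
  ## is lambda * sum(f_c) and lambda must be scaled by the copy total for
  ## the side mean to equal mu
  genomeCopies <- sum(cf$fractions)
  lambda <- stats::rgamma(N, shape = theta, scale = mu / genomeCopies / theta)

  ## per division, per side, per copy: Poisson counts and Bernoulli masks
  divs <- integer(); grps <- character(); chroms <- character()
  for (n in seq_len(N)) {
    for (side in c("daughter", "mother")) {
      counts <- stats::rpois(nc, lambda[n] * cf$fractions)
      keepMask <- stats::rbinom(nc, 1L, 0.5)  # 1 = Da (daughter side) / Ma (mother side)
      g <- if (side == "daughter") ifelse(keepMask == 1L, "Da", "Db")
           else ifelse(keepMask == 1L, "Ma", "Mb")
      tot <- sum(counts)
      if (tot) {
        divs <- c(divs, rep(n, tot))
        grps <- c(grps, rep(g, counts))
        chroms <- c(chroms, rep(cn[cf$chrom], counts))
      }
    }
  }
  nEv <- length(divs)

  ## colony-private noise events, drawn per colony
  nCol <- 4L * N
  noiseN <- if (noiseRate > 0) stats::rpois(nCol, noiseRate) else integer(nCol)
  noiseChrom <- if (sum(noiseN))
    sample(cn, sum(noiseN), replace = TRUE, prob = chromFractions(chromset))
  else character()

  ## positions unique within the lineage (sampled without replacement
  ## per chromosome across truth + noise events)
  allChrom <- c(chroms, noiseChrom)
  allPos <- .samplePositions(allChrom, chromset)
  allAlt <- sample(c("C", "G", "T"), length(allChrom), replace = TRUE)
  allKey <- paste(allChrom, allPos, allAlt, sep = ":")

  pos <- allPos[seq_len(nEv)]
  alt <- allAlt[seq_len(nEv)]
  key <- allKey[seq_len(nEv)]

  ## which colonies carry each truth event
  ## colony order within a sublineage: D, GD1, GD2, GGD
  colonyOf <- function(m, p) (m - 1L) * 4L + match(p, .POSITIONS)
  carrier <- vector("list", nEv)
  observed <- logical(nEv)
  idxByDivGrp <- split(seq_len(nEv), list(divs, grps), drop = TRUE)
  for (nm in names(idxByDivGrp)) {
    ii <- idxByDivGrp[[nm]]
    n <- divs[ii[1L]]
    g <- grps[ii[1L]]
    cols <- switch(g,
      Da = c(colonyOf(n, "D"), colonyOf(n, "GD2")),
      Db = c(colonyOf(n, "GD1"), colonyOf(n, "GGD")),
      Ma = if (n + 1L <= N) vapply(.POSITIONS, function(p) colonyOf(n + 1L, p),
                                   integer(1)) else integer(),
      Mb = if (n + 2L <= N)
        unlist(lapply((n + 2L):N, function(m)
          vapply(.POSITIONS, function(p) colonyOf(m, p), integer(1))))
      else integer()
    )
    carrier[ii] <- list(as.integer(cols))
    observed[ii] <- length(cols) > 0L
  }

  ## assemble per-colony variant index lists (into the master event table)
  colIdx <- vector("list", nCol)
  for (i in seq_len(nCol)) colIdx[[i]] <- integer()
  if (nEv) {
    colRep <- unlist(carrier)
    idxRep <- rep(seq_len(nEv), lengths(carrier))
    byCol <- split(idxRep, colRep)
    colIdx[as.integer(names(byCol))] <- byCol
  }
  ## append noise singletons
  if (sum(noiseN)) {
    noiseIdx <- (nEv + 1L):length(allKey)
    noiseCol <- rep(seq_len(nCol), noiseN)
    byCol <- split(noiseIdx, noiseCol)
    for (nm in names(byCol))
      colIdx[[as.integer(nm)]] <- c(colIdx[[as.integer(nm)]], byCol[[nm]])
  }

  si <- .seqinfo(chromset)
  wholeGenome <- GenomicRanges::GRanges(cn, IRanges::IRanges(1L, chromLengths(chromset)),
                                        seqinfo = si)
  ## one master GRanges; colony variant sets are subsets of it
  grAll <- GenomicRanges::GRanges(allChrom, IRanges::IRanges(allPos, width = 1L),
                                  seqinfo = si)
  S4Vectors::mcols(grAll)$ref <- rep("A", length(grAll))
  S4Vectors::mcols(grAll)$alt <- allAlt
  makeCallable <- function() {
    if (maskFraction <= 0) return(wholeGenome)
    lens <- chromLengths(chromset)
    drop <- round(lens * maskFraction)
    startMax <- pmax(lens - drop, 1)
    s <- vapply(startMax, function(sm) sample.int(sm, 1L), integer(1))
    masked <- GenomicRanges::GRanges(cn, IRanges::IRanges(s, width = pmax(drop, 1)),
                                     seqinfo = si)
    GenomicRanges::setdiff(wholeGenome, masked, ignore.strand = TRUE)
  }

  colonies <- vector("list", nCol)
  for (m in seq_len(N)) {
    for (p in .POSITIONS) {
      i <- colonyOf(m, p)
      colonies[[i]] <- ColonyRecord(
        colonyId = sprintf("%s%d.%s", "SL", m, p),
        division = m, position = p,
        variants = grAll[colIdx[[i]]],
        callable = makeCallable())
    }
  }

  truth <- data.frame(
    key = c(key, if (sum(noiseN)) allKey[(nEv + 1L):length(allKey)]),
    chrom = allChrom, pos = allPos, ref = "A", alt = allAlt,
    division = c(divs, rep(NA_integer_, sum(noiseN))),
    group = c(grps, rep(NA_character_, sum(noiseN))),
    observed = c(observed, rep(TRUE, sum(noiseN))),
    noise = c(rep(FALSE, nEv), rep(TRUE, sum(noiseN))),
    stringsAsFactors = FALSE)

  list(lineage = LineageTable(colonies, chromset), truth = truth,
       lambda = lambda)
}

#' Corrupt a synthetic lineage with a documented assignment error
#'
#' Rewires colony contents to mimic the physical mix-ups that can occur at
#' dissection:
#' \describe{
#'   \item{`"Dn1_for_GDn1"`}{the mother's next daughter Dn+1 is moved in
#'     place of GDn.1; sublineage n receives Dn+1 and her daughter, and
#'     sublineage n+1 consists entirely of descendants of Dn (four
#'     identical colonies).}
#'   \item{`"GDn1_GDn2_swap"`}{the two granddaughters are interchanged,
#'     so the great-granddaughter is isolated from the wrong branch.}
#'   \item{`"GGDn1_GGDn2_swap"`}{the second great-granddaughter is taken
#'     instead of the first; the inheritance pattern is undistorted (a
#'     documented detection blind spot) but the Db count absorbs the
#'     errors of an extra division, injected here as additional shared
#'     GDn.1/GGDn.1 variants.}
#' }
#'
#' @param sim output of [generateLineage()] (lineage plus ground truth).
#' @param division the division n at which the mix-up happens; must be
#'   scorable in the clean lineage.
#' @param type one of the three error types above.
#' @param seed optional RNG seed (used by `"GGDn1_GGDn2_swap"` to draw the
#'   extra-division events).
#' @return the corrupted [LineageTable-class].
#' @export
injectAssignmentError <- function(sim, division,
                                  type = c("Dn1_for_GDn1", "GDn1_GDn2_swap",
                                           "GGDn1_GGDn2_swap"),
                                  seed = NULL) {
  type <- match.arg(type)
  lineage <- sim$lineage
  truth <- sim$truth
  N <- nSublineages(lineage)
  n <- as.integer(division)
  if (n < 1L || n + 3L > N)
    stop("division must be scorable in the clean lineage")
  if (!is.null(seed)) set.seed(seed)

  getCol <- function(m, p) lineageColony(lineage, m, p)
  setVars <- function(lt, m, p, gr) {
    for (i in seq_along(lt@colonies)) {
      cc <- lt@colonies[[i]]
      if (cc@division == m && cc@position == p) {
        ## keep the colony's own private noise on top of the rewired content
        noiseKeys <- intersect(.variantKeys(cc@variants),
                               truth$key[truth$noise])
        keep <- cc@variants[.variantKeys(cc@variants) %in% noiseKeys]
        cc@variants <- sort(c(gr[!.variantKeys(gr) %in% truth$key[truth$noise]],
                              keep))
        lt@colonies[[i]] <- cc
        return(lt)
      }
    }
    lt
  }

  if (type == "Dn1_for_GDn1") {
    ## sublineage n gets Dn+1 and her first daughter in the GD1/GGD slots;
    ## sublineage n+1 becomes four colonies of GDn.1-descendant content
    dNext <- getCol(n + 1L, "D")@variants
    gdNext <- getCol(n + 1L, "GD1")@variants
    gd1 <- getCol(n, "GD1")@variants
    lineage <- setVars(lineage, n, "GD1", dNext)
    lineage <- setVars(lineage, n, "GGD", gdNext)
    for (p in .POSITIONS)
      lineage <- setVars(lineage, n + 1L, p, gd1)
  } else if (type == "GDn1_GDn2_swap") {
    gd1 <- getCol(n, "GD1")@variants
    gd2 <- getCol(n, "GD2")@variants
    lineage <- setVars(lineage, n, "GD1", gd2)
    lineage <- setVars(lineage, n, "GD2", gd1)
    ## the isolated great-granddaughter is a daughter of (actual) GDn.2,
    ## which carries the same double-stranded content as GDn.2
    lineage <- setVars(lineage, n, "GGD", gd2)
  } else {  # GGDn1_GGDn2_swap
    ## content is indistinguishable; the extra division of GDn.1 adds
    ## ~lambda/2 new shared mutations to the putative Db comparison
    lamExtra <- stats::rgamma(1L, shape = 60.42, scale = mean(sim$lambda) / 60.42)
    kExtra <- stats::rpois(1L, lamExtra / 2)
    if (kExtra > 0L) {
      cs <- lineage@chromset
      chrom <- sample(chromNames(cs), kExtra, replace = TRUE,
                      prob = chromFractions(cs))
      pos <- .samplePositions(chrom, cs)
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                   seqinfo = .seqinfo(cs))
      S4Vectors::mcols(gr)$ref <- rep("A", kExtra)
      S4Vectors::mcols(gr)$alt <- sample(c("C", "G", "T"), kExtra, replace = TRUE)
      for (p in c("GD1", "GGD")) {
        cc <- getCol(n, p)
        merged <- sort(c(cc@variants, gr))
        lineage <- setVars(lineage, n, p, merged)
      }
    }
  }
  lineage
}

#' Generate an i.i.d. count sample from a named model
#'
#' Front-end for testing the count-model fitters: `"poisson"` (params:
#' `lambda`), `"poisson_mixture"` (`p`, `lambda`), `"negbin"` (`mu`,
#' `theta`) and `"gamma_poisson"` (`mu`, `theta`; an explicit
#' gamma-then-Poisson compound, distributionally identical to the negative
#' binomial).
#'
#' @param model model name.
#' @param params named list of parameters (see above).
#' @param n sample size.
#' @param seed optional RNG seed.
#' @return integer vector of counts.
#' @export
generateCountSample <- function(model = c("poisson", "poisson_mixture",
                                          "negbin", "gamma_poisson"),
                                params, n, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  switch(model,
    poisson = {
      if (is.null(params$lambda) || params$lambda <= 0)
        stop("poisson requires lambda > 0")
      stats::rpois(n, params$lambda)
    },
    poisson_mixture = {
      p <- params$p; lam <- params$lambda
      if (is.null(p) || is.null(lam) || length(p) != length(lam) ||
          abs(sum(p) - 1) > 1e-8 || any(lam <= 0))
        stop("poisson_mixture requires weights summing to 1 and positive lambda")
      comp <- sample.int(length(p), n, replace = TRUE, prob = p)
      stats::rpois(n, lam[comp])
    },
    negbin = {
      if (is.null(params$mu) || is.null(params$theta) ||
          params$mu <= 0 || params$theta <= 0)
        stop("negbin requires mu, theta > 0")
      stats::rnbinom(n, size = params$theta, mu = params$mu)
    },
    gamma_poisson = {
      if (is.null(params$mu) || is.null(params$theta) ||
          params$mu <= 0 || params$theta <= 0)
        stop("gamma_poisson requires mu, theta > 0")
      lam <- stats::rgamma(n, shape = params$theta,
                           scale = params$mu / params$theta)
      stats::rpois(n, lam)
    })
}
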