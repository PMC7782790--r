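## Segregant-group mutation calling.
##
## Replication errors from maternal division n distribute over the pedigree
## in four mutually exclusive presence patterns:
##   Da(n): in Dn and GDn.2 only        (daughter-retained errors)
##   Db(n): in GDn.1 and GGDn.1 only    (errors passed to the granddaughter)
##   Ma(n): in all four colonies of sublineage n+1 only
##   Mb(n): in every colony of every sublineage >= n+2, absent before
## Their sum is the division's full error count; Dm = Da + Db and
## Mm = Ma + Mb are the mismatches segregated to daughter and mother.
## Any variant matching none of the patterns is kept in an "unassigned"
## residue (never silently dropped); structured residues are the raw
## material of assignment-error detection.

#' Shared callable genome of a colony set
#'
#' Intersection of the callable intervals of the named colonies (all
#' colonies by default), the genomic territory on which every lineage
#' member could have been scored.
#'
#' @param lineage a [LineageTable-class].
#' @param members optional character vector of colony ids to restrict to.
#' @return list with `intervals` (GRanges) and `lengths` (named per-
#'   chromosome shared bp).
#' @export
sharedCallableGenome <- function(lineage, members = NULL) {
  ci <- .colonyIndex(lineage)
  use <- lineage@colonies
  if (!is.null(members)) {
    if (!length(members)) stop("members must name at least one colony")
    miss <- setdiff(members, ci$id)
    if (length(miss)) stop("unknown colony ids: ", paste(miss, collapse = ", "))
    use <- use[ci$idx[match(members, ci$id)]]
  }
  allSame <- length(use) == 1L ||
    all(vapply(use[-1L], function(cc)
      identical(cc@callable, use[[1L]]@callable), logical(1)))
  if (allSame) {
    shared <- GenomicRanges::reduce(use[[1L]]@callable)
  } else {
    ## intersection of K interval sets = territory covered by all K
    pooled <- do.call(c, lapply(use, function(cc)
      GenomicRanges::granges(GenomicRanges::reduce(cc@callable))))
    cov <- GenomicRanges::coverage(pooled)
    shared <- methods::as(IRanges::slice(cov, lower = length(use),
                                         rangesOnly = TRUE), "GRanges")
    GenomeInfoDb::seqinfo(shared) <- .seqinfo(lineage@chromset)
  }
  lens <- stats::setNames(rep(0, length(lineage@chromset)),
                          chromNames(lineage@chromset))
  if (length(shared)) {
    w <- tapply(BiocGenerics::width(shared),
                as.character(GenomeInfoDb::seqnames(shared)), sum)
    lens[names(w)] <- w
  }
  list(intervals = shared, lengths = lens)
}

#' Restrict a lineage to its shared genome and multi-colony variants
#'
#' Filters every colony's variants to positions inside the shared callable
#' genome of the whole lineage, then removes variants observed in only one
#' colony (singletons are indistinguishable from sequencing errors or
#' within-colony clonal sweeps).
#'
#' @param lineage a [LineageTable-class].
#' @return A filtered [LineageTable-class].
#' @export
filterToShared <- function(lineage) {
  shared <- sharedCallableGenome(lineage)$intervals
  wholeGenome <- sum(as.numeric(BiocGenerics::width(shared))) >=
    sum(chromLengths(lineage@chromset))
  cols <- if (wholeGenome) lineage@colonies else
    lapply(lineage@colonies, function(cc) {
      cc@variants <- IRanges::subsetByOverlaps(cc@variants, shared,
                                               ignore.strand = TRUE)
      cc
    })
  ## drop lineage-wide singletons
  keys <- lapply(cols, function(cc) .variantKeys(cc@variants))
  tab <- table(unlist(keys, use.names = FALSE))
  multi <- names(tab)[tab >= 2L]
  cols <- mapply(function(cc, k) {
    cc@variants <- cc@variants[k %in% multi]
    cc
  }, cols, keys, SIMPLIFY = FALSE)
  LineageTable(cols, lineage@chromset, censored = lineage@censored)
}

## ----------------------------------------------------- SegregantCounts ----

#' SegregantCounts: per-division Da/Db/Ma/Mb tallies
#'
#' @slot division the scored maternal division.
#' @slot counts named integer vector `Da, Db, Ma, Mb`.
#' @slot perChromosome integer matrix, chromosomes x the four groups;
#'   column sums equal `counts`.
#' @slot unassigned keys of variants attributed to this division that match
#'   no segregant pattern.
#' @slot scorable FALSE when required sublineages are missing or censored
#'   (counts are then NA, not zero).
#' @export
setClass("SegregantCounts",
  slots = c(division = "integer", counts = "numeric",
            perChromosome = "matrix", unassigned = "character",
            scorable = "logical"))

setValidity("SegregantCounts", function(object) {
  msg <- character()
  if (!identical(names(object@counts), c("Da", "Db", "Ma", "Mb")))
    msg <- c(msg, "counts must be named Da, Db, Ma, Mb")
  if (object@scorable) {
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(colSums(object@perChromosome) - object@counts) > 0))
      msg <- c(msg, "per-chromosome columns must sum to the scalar counts")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegregantCounts", function(object) {
  if (!object@scorable) {
    cat(sprintf("SegregantCounts division %d: not scorable (censored/missing sublineages)\n",
                object@division))
    return(invisible(NULL))
  }
  cat(sprintf("SegregantCounts division %d: Da %d, Db %d, Ma %d, Mb %d (full %d, %d unassigned)\n",
              object@division, object@counts[["Da"]], object@counts[["Db"]],
              object@counts[["Ma"]], object@counts[["Mb"]],
              sum(object@counts), length(object@unassigned)))
})

#' @rdname SegregantCounts
#' @param x a `SegregantCounts`.
#' @export
setGeneric("fullErrorCount", function(x) standardGeneric("fullErrorCount"))

#' @rdname SegregantCounts
#' @export
setMethod("fullErrorCount", "SegregantCounts", function(x) {
  if (!x@scorable) return(NA_real_)
  sum(x@counts)
})

#' @rdname SegregantCounts
#' @export
setGeneric("mismatchCounts", function(x) standardGeneric("mismatchCounts"))

#' @rdname SegregantCounts
#' @export
setMethod("mismatchCounts", "SegregantCounts", function(x) {
  if (!x@scorable) return(c(Dm = NA_real_, Mm = NA_real_))
  c(Dm = unname(x@counts[["Da"]] + x@counts[["Db"]]),
    Mm = unname(x@counts[["Ma"]] + x@counts[["Mb"]]))
})

## colony list-index for (division, position), NA if absent/censored
.posIdx <- function(ci, censored, division, position) {
  i <- which(ci$division == division & ci$position == position &
               !(ci$division %in% censored))
  if (length(i)) i else NA_integer_
}

## core assignment over all divisions; returns incidence plus per-key
## division/group assignment (NA where unmatched)
.assignAll <- function(lineage) {
  inc <- .lineageIncidence(lineage)
  ci <- inc$colonyIndex
  N <- nSublineages(lineage)
  cens <- lineage@censored
  live <- setdiff(seq_len(N), cens)

  idx <- function(m, p) .posIdx(ci, cens, m, p)
  subCols <- lapply(seq_len(N), function(m)
    sort(c(idx(m, "D"), idx(m, "GD1"), idx(m, "GD2"), idx(m, "GGD"))))

  nKeys <- length(inc$keys)
  presentCount <- rowSums(inc$present)
  ## binary presence fingerprint per key for exact pattern matching
  nCol <- ncol(inc$present)
  patStr <- if (nKeys)
    do.call(paste0, lapply(seq_len(nCol), function(j)
      as.integer(inc$present[, j])))
  else character()
  binPat <- function(idx) paste(as.integer(seq_len(nCol) %in% idx),
                                collapse = "")

  division <- rep(NA_integer_, nKeys)
  group <- rep(NA_character_, nKeys)

  scorable <- logical(N)
  for (n in seq_len(N)) {
    need <- n:(n + 3L)
    scorable[n] <- all(need <= N) && !any(need %in% cens)
    if (!scorable[n]) next
    pats <- c(
      Da = binPat(c(idx(n, "D"), idx(n, "GD2"))),
      Db = binPat(c(idx(n, "GD1"), idx(n, "GGD"))),
      Ma = binPat(subCols[[n + 1L]]),
      Mb = binPat(unlist(subCols[live[live >= n + 2L]]))
    )
    for (g in names(pats)) {
      hit <- which(patStr == pats[[g]] & is.na(group))
      if (length(hit)) {
        division[hit] <- n
        group[hit] <- g
      }
    }
  }

  ## unmatched keys: attribute to the earliest sublineage of appearance
  unmatched <- which(is.na(group) & presentCount > 0L)
  earliest <- rep(NA_integer_, nKeys)
  if (length(unmatched))
    earliest[unmatched] <- vapply(unmatched, function(i)
      min(ci$division[inc$present[i, ]]), integer(1))

  list(inc = inc, division = division, group = group, earliest = earliest,
       scorable = scorable, subCols = subCols, idx = idx, patStr = patStr,
       binPat = binPat)
}

.countsForDivision <- function(asg, chromset, n) {
  groups <- c("Da", "Db", "Ma", "Mb")
  cn <- chromNames(chromset)
  if (!asg$scorable[n]) {
    return(new("SegregantCounts", division = as.integer(n),
               counts = stats::setNames(rep(NA_real_, 4L), groups),
               perChromosome = matrix(NA_integer_, length(cn), 4L,
                                      dimnames = list(cn, groups)),
               unassigned = character(), scorable = FALSE))
  }
  pc <- matrix(0L, nrow = length(cn), ncol = 4L, dimnames = list(cn, groups))
  sel <- which(asg$division == n)
  if (length(sel)) {
    t2 <- table(factor(asg$inc$chrom[sel], levels = cn),
                factor(asg$group[sel], levels = groups))
    pc[] <- as.integer(t2)
  }
  unas <- asg$inc$keys[which(is.na(asg$group) & asg$earliest == n)]
  new("SegregantCounts", division = as.integer(n),
      counts = colSums(pc)[groups],
      perChromosome = pc, unassigned = unas, scorable = TRUE)
}

#' Assign segregant groups for one division
#'
#' Classifies every lineage variant by its presence/absence pattern and
#' returns the Da/Db/Ma/Mb tallies for division `n`. The division is
#' scorable only when sublineages `n` through `n + 3` are present and
#' uncensored (Mb requires the two following daughters); otherwise the
#' returned counts are NA. Run [filterToShared()] first.
#'
#' @param lineage a (filtered) [LineageTable-class].
#' @param n division index.
#' @return A [SegregantCounts-class].
#' @export
assignSegregantGroups <- function(lineage, n) {
  if (n < 1L || n > nSublineages(lineage)) stop("division out of range")
  .countsForDivision(.assignAll(lineage), lineage@chromset, as.integer(n))
}

#' Call all scorable divisions of a lineage
#'
#' Applies [filterToShared()] (optional) and assigns segregant groups for
#' every division.
#'
#' @param lineage a [LineageTable-class].
#' @param filter apply [filterToShared()] first (default TRUE).
#' @return list with `counts` (list of [SegregantCounts-class], one per
#'   division) and `summary` (the [segregantSummary()] data.frame).
#' @export
callLineage <- function(lineage, filter = TRUE) {
  if (filter) lineage <- filterToShared(lineage)
  asg <- .assignAll(lineage)
  N <- nSublineages(lineage)
  counts <- lapply(seq_len(N), function(n)
    .countsForDivision(asg, lineage@chromset, n))
  list(counts = counts, summary = segregantSummary(counts))
}

#' Tabulate per-division segregant counts
#'
#' @param counts list of [SegregantCounts-class].
#' @return data.frame with division, Da, Db, Ma, Mb, Dm, Mm, full,
#'   unassigned and censored columns (unscorable divisions carry NA counts).
#' @export
segregantSummary <- function(counts) {
  do.call(rbind, lapply(counts, function(sc) {
    mm <- mismatchCounts(sc)
    data.frame(division = sc@division,
               Da = sc@counts[["Da"]], Db = sc@counts[["Db"]],
               Ma = sc@counts[["Ma"]], Mb = sc@counts[["Mb"]],
               Dm = unname(mm["Dm"]), Mm = unname(mm["Mm"]),
               full = fullErrorCount(sc),
               unassigned = length(sc@unassigned),
               censored = !sc@scorable,
               row.names = NULL)
  }))
}

## --------------------------------------------------- segregation tally ----

#' SegregationTally: per-chromosome inheritance classes
#'
#' For a pair of segregant groups, each chromosome carrying at least one
#' mutation falls in class `all` (first group inherited 100%), `none` (0%)
#' or `partial` (any strictly intermediate fraction). Under all-or-none
#' segregation of two homologous copies the classes appear 1:2:1.
#'
#' @slot counts named integer vector `none, partial, all`.
#' @slot fractions the per-chromosome fractions observed in the first group.
#' @export
setClass("SegregationTally",
  slots = c(counts = "integer", fractions = "numeric"))

setMethod("show", "SegregationTally", function(object) {
  cat(sprintf("SegregationTally: none %d, partial %d, all %d (n = %d)\n",
              object@counts[["none"]], object@counts[["partial"]],
              object@counts[["all"]], sum(object@counts)))
})

#' Classify per-chromosome segregation of a segregant-group pair
#'
#' @param counts a [SegregantCounts-class] or list of them (tally
#'   accumulates across divisions; unscorable divisions are skipped).
#' @param pair `"Da/Db"` or `"Ma/Mb"`; the fraction reported is the first
#'   member's share.
#' @return A [SegregationTally-class].
#' @export
classifySegregation <- function(counts, pair = c("Da/Db", "Ma/Mb")) {
  pair <- match.arg(pair)
  gg <- strsplit(pair, "/", fixed = TRUE)[[1L]]
  if (is(counts, "SegregantCounts")) counts <- list(counts)
  fracs <- numeric()
  for (sc in counts) {
    if (!sc@scorable) next
    a <- sc@perChromosome[, gg[1L]]
    b <- sc@perChromosome[, gg[2L]]
    tot <- a + b
    keep <- tot > 0L
    fracs <- c(fracs, a[keep] / tot[keep])
  }
  cls <- ifelse(fracs == 1, "all", ifelse(fracs == 0, "none", "partial"))
  new("SegregationTally",
      counts = c(none = sum(cls == "none"), partial = sum(cls == "partial"),
                 all = sum(cls == "all")),
      fractions = unname(fracs))
}

## ------------------------------------------------- assignment errors ----

#' Detect pedigree assignment errors
#'
#' Scans a (filtered) lineage for the structured deviations that physical
#' mix-ups at dissection leave behind:
#' \describe{
#'   \item{`Ma_zero_recurring_Db`}{a sublineage with zero Ma mutations in
#'     which a substantial fraction (> 25%) of the putative Db variants
#'     recur in later sublineages — the signature of the next daughter
#'     having been moved in place of the first granddaughter.}
#'   \item{`identical_sublineage`}{all four colonies of a sublineage share
#'     an identical variant set, i.e. they all descend from a single
#'     daughter, so the sublineage contributes zero Mb mutations.}
#'   \item{`Da_matches_Ma`}{a division with zero Da and Db counts whose
#'     residue contains variants spanning Dn, GDn.1 and GGDn.1 — the
#'     signature of swapped granddaughters, whose putative Da comparison
#'     returns mutations that are really Ma of the previous division.}
#' }
#' Clean lineages return a zero-row table. Flagged sublineages can be
#' passed to [censorLineage()].
#'
#' @param lineage a [LineageTable-class] (filtered with [filterToShared()]
#'   if it has not been already).
#' @param filter apply [filterToShared()] first (default TRUE).
#' @return data.frame with columns `division`, `sublineage`, `signature`,
#'   `support` (number of variants behind the flag) and `censor`
#'   (comma-separated suggested censor set).
#' @export
detectAssignmentErrors <- function(lineage, filter = TRUE) {
  if (filter) lineage <- filterToShared(lineage)
  asg <- .assignAll(lineage)
  inc <- asg$inc
  ci <- inc$colonyIndex
  N <- nSublineages(lineage)
  cens <- lineage@censored
  live <- setdiff(seq_len(N), cens)
  m <- inc$present

  flags <- data.frame(division = integer(), sublineage = integer(),
                      signature = character(), support = integer(),
                      censor = character(), stringsAsFactors = FALSE)
  addFlag <- function(div, sub, sig, support, censor) {
    flags[nrow(flags) + 1L, ] <<- list(as.integer(div), as.integer(sub), sig,
                                       as.integer(support),
                                       paste(censor, collapse = ","))
  }
  if (!length(inc$keys)) return(flags)

  grpCount <- function(n, g) sum(asg$division == n & asg$group == g, na.rm = TRUE)
  colsOfSub <- function(s) asg$subCols[[s]]

  ## (a) zero Ma with recurring putative Db
  for (s in live[live >= 2L & live <= N - 2L]) {
    if (!asg$scorable[s - 1L]) next
    if (grpCount(s - 1L, "Ma") > 0L) next
    iD <- asg$idx(s, "D"); iGD1 <- asg$idx(s, "GD1")
    iGD2 <- asg$idx(s, "GD2"); iGGD <- asg$idx(s, "GGD")
    if (anyNA(c(iD, iGD1, iGD2, iGGD))) next
    earlier <- unlist(lapply(live[live < s], colsOfSub))
    later <- unlist(lapply(live[live > s], colsOfSub))
    putDb <- m[, iGD1] & m[, iGGD] & !m[, iD] & !m[, iGD2]
    if (length(earlier)) putDb <- putDb & !rowSums(m[, earlier, drop = FALSE])
    nDb <- sum(putDb)
    if (nDb == 0L) next
    recur <- putDb & rowSums(m[, later, drop = FALSE]) > 0L
    if (sum(recur) / nDb > 0.25)
      addFlag(s, s, "Ma_zero_recurring_Db", nDb, c(s, s + 1L))
  }

  ## (b) a sublineage whose colonies are all identical (one-daughter descent)
  for (s in live) {
    cols <- colsOfSub(s)
    if (length(cols) != 4L) next
    inSub <- rowSums(m[, cols, drop = FALSE])
    touched <- inSub > 0L
    if (!any(touched)) next
    if (all(inSub[touched] == 4L)) {
      ## every variant seen in the sublineage is in all four colonies:
      ## no Da/Db/Ma structure at all
      addFlag(max(s - 2L, 1L), s, "identical_sublineage", sum(touched), s)
    }
  }

  ## (c) swapped granddaughters: Da and Db empty, residue spans D+GD1+GGD
  for (n in which(asg$scorable)) {
    if (grpCount(n, "Da") > 0L || grpCount(n, "Db") > 0L) next
    iD <- asg$idx(n, "D"); iGD1 <- asg$idx(n, "GD1")
    iGD2 <- asg$idx(n, "GD2"); iGGD <- asg$idx(n, "GGD")
    pat <- asg$binPat(c(iD, iGD1, iGGD))
    hit <- sum(asg$patStr == pat & is.na(asg$group))
    if (hit > 0L)
      addFlag(n, n, "Da_matches_Ma", hit, n)
  }
  flags
}
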