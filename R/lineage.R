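## Single-cell pedigree containers.
##
## A lineage is an ordered series of "sublineages", one per scored maternal
## division n. Each sublineage holds four sequenced colonies grown from the
## daughter (Dn), her first and second daughters (GDn.1, GDn.2) and the
## first granddaughter born to GDn.1 (GGDn.1). The presence/absence pattern
## of a mutation across these colonies determines the segregant group
## (Da/Db/Ma/Mb) and hence the division in which the underlying replication
## error arose.

.POSITIONS <- c("D", "GD1", "GD2", "GGD")

#' ColonyRecord: one sequenced colony of a pedigree
#'
#' @slot colonyId unique colony identifier.
#' @slot division the sublineage (maternal division) index, >= 1.
#' @slot position pedigree role within the sublineage: `"D"`, `"GD1"`,
#'   `"GD2"` or `"GGD"`.
#' @slot variants width-1 [GenomicRanges::GRanges] of single-nucleotide
#'   variants with metadata columns `ref` and `alt`; variants at the same
#'   position with different alt alleles are distinct mutations.
#' @slot callable [GenomicRanges::GRanges] of confidently callable regions.
#' @export
setClass("ColonyRecord",
  slots = c(colonyId = "character", division = "integer",
            position = "character", variants = "GRanges",
            callable = "GRanges"))

setValidity("ColonyRecord", function(object) {
  msg <- character()
  if (length(object@colonyId) != 1L) msg <- c(msg, "colonyId must be scalar")
  if (length(object@division) != 1L || object@division < 1L)
    msg <- c(msg, "division must be a positive integer")
  if (!object@position %in% .POSITIONS)
    msg <- c(msg, "position must be one of D, GD1, GD2, GGD")
  if (length(object@variants) &&
      !all(c("ref", "alt") %in% names(S4Vectors::mcols(object@variants))))
    msg <- c(msg, "variants must carry ref and alt metadata columns")
  if (length(msg)) msg else TRUE
})

#' Construct a ColonyRecord
#'
#' @param colonyId unique identifier.
#' @param division sublineage index (>= 1).
#' @param position `"D"`, `"GD1"`, `"GD2"` or `"GGD"`.
#' @param variants GRanges of SNVs with `ref`/`alt` metadata (may be empty).
#' @param callable GRanges of callable intervals.
#' @return A [ColonyRecord-class].
#' @export
ColonyRecord <- function(colonyId, division, position, variants, callable) {
  new("ColonyRecord", colonyId = as.character(colonyId),
      division = as.integer(division), position = as.character(position),
      variants = variants, callable = callable)
}

setMethod("show", "ColonyRecord", function(object) {
  cat(sprintf("ColonyRecord %s (division %d, %s): %d variants, %d callable intervals\n",
              object@colonyId, object@division, object@position,
              length(object@variants), length(object@callable)))
})

#' LineageTable: a complete single-cell pedigree
#'
#' Ordered colonies of consecutive sublineages plus the karyotype they were
#' called against. Sublineages flagged in `censored` are excluded from
#' scoring (e.g. after an assignment error was detected).
#'
#' @slot colonies list of [ColonyRecord-class], four per sublineage.
#' @slot chromset the [ChromosomeSet-class] in force.
#' @slot censored integer vector of censored sublineage indices.
#' @export
setClass("LineageTable",
  slots = c(colonies = "list", chromset = "ChromosomeSet",
            censored = "integer"))

setValidity("LineageTable", function(object) {
  msg <- character()
  if (!all(vapply(object@colonies, is, logical(1), "ColonyRecord")))
    msg <- c(msg, "colonies must all be ColonyRecord objects")
  div <- vapply(object@colonies, function(cc) cc@division, integer(1))
  pos <- vapply(object@colonies, function(cc) cc@position, character(1))
  if (length(div)) {
    if (!setequal(unique(div), seq_len(max(div))))
      msg <- c(msg, "sublineages must be numbered consecutively from 1")
    byDiv <- split(pos, div)
    if (!all(vapply(byDiv, function(p) setequal(p, .POSITIONS), logical(1))))
      msg <- c(msg, "each sublineage needs exactly the D, GD1, GD2, GGD colonies")
  }
  ids <- vapply(object@colonies, function(cc) cc@colonyId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "colony ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a LineageTable
#'
#' @param colonies list of [ColonyRecord-class]s (four per sublineage,
#'   consecutive divisions from 1).
#' @param chromset a [ChromosomeSet-class].
#' @param censored integer vector of censored sublineage indices.
#' @return A [LineageTable-class].
#' @export
LineageTable <- function(colonies, chromset, censored = integer()) {
  new("LineageTable", colonies = colonies, chromset = chromset,
      censored = as.integer(censored))
}

setMethod("show", "LineageTable", function(object) {
  cat(sprintf("LineageTable: %d sublineages (%d colonies), %d censored\n",
              nSublineages(object), length(object@colonies),
              length(object@censored)))
  nv <- sum(vapply(object@colonies, function(cc) length(cc@variants), integer(1)))
  cat(sprintf("  %d variant records across colonies; karyotype of %d chromosomes\n",
              nv, length(object@chromset)))
})

#' @rdname LineageTable
#' @param x a `LineageTable`.
#' @export
setGeneric("nSublineages", function(x) standardGeneric("nSublineages"))

#' @rdname LineageTable
#' @export
setMethod("nSublineages", "LineageTable", function(x) {
  if (!length(x@colonies)) return(0L)
  max(vapply(x@colonies, function(cc) cc@division, integer(1)))
})

#' Retrieve one colony of a lineage
#'
#' @param lineage a [LineageTable-class].
#' @param division sublineage index.
#' @param position `"D"`, `"GD1"`, `"GD2"` or `"GGD"`.
#' @return The matching [ColonyRecord-class], or NULL if absent.
#' @export
lineageColony <- function(lineage, division, position) {
  for (cc in lineage@colonies)
    if (cc@division == division && cc@position == position) return(cc)
  NULL
}

#' Mark sublineages as censored
#'
#' @param lineage a [LineageTable-class].
#' @param sublineages integer indices to censor (added to any existing).
#' @return The updated lineage.
#' @export
censorLineage <- function(lineage, sublineages) {
  lineage@censored <- sort(unique(c(lineage@censored, as.integer(sublineages))))
  lineage
}

## variant keys "chrom:pos:alt" (ref is redundant given position)
.variantKeys <- function(gr) {
  if (!length(gr)) return(character())
  paste(as.character(GenomeInfoDb::seqnames(gr)),
        BiocGenerics::start(gr),
        S4Vectors::mcols(gr)$alt, sep = ":")
}

## index of colonies: one row per colony, in list order
.colonyIndex <- function(lineage) {
  data.frame(
    idx = seq_along(lineage@colonies),
    id = vapply(lineage@colonies, function(cc) cc@colonyId, character(1)),
    division = vapply(lineage@colonies, function(cc) cc@division, integer(1)),
    position = vapply(lineage@colonies, function(cc) cc@position, character(1)),
    stringsAsFactors = FALSE)
}

## incidence of variant keys across uncensored colonies:
## keys, chrom/pos/alt lookup, and a logical keys x colonies matrix
.lineageIncidence <- function(lineage) {
  ci <- .colonyIndex(lineage)
  keep <- !(ci$division %in% lineage@censored)
  keysBy <- lapply(lineage@colonies, function(cc) .variantKeys(cc@variants))
  keysBy[!keep] <- list(character())
  allKeys <- unlist(keysBy, use.names = FALSE)
  keys <- unique(allKeys)
  m <- matrix(FALSE, nrow = length(keys), ncol = nrow(ci))
  rows <- match(allKeys, keys)
  cols <- rep(ci$idx, lengths(keysBy))
  m[cbind(rows, cols)] <- TRUE
  parts <- strsplit(keys, ":", fixed = TRUE)
  list(keys = keys,
       chrom = vapply(parts, `[[`, character(1), 1L),
       present = m,
       colonyIndex = ci)
}
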