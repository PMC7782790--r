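## Karyotype representation: chromosome names, lengths and genome fractions.
## All per-chromosome simulation and the segregation classifier are
## parameterized by these fractions f_i = length_i / total length.

# S288C (sacCer3, R64) nuclear chromosomes, bp
.YEAST_S288C <- c(
  chrI = 230218L,  chrII = 813184L,   chrIII = 316620L, chrIV = 1531933L,
  chrV = 576874L,  chrVI = 270161L,   chrVII = 1090940L, chrVIII = 562643L,
  chrIX = 439888L, chrX = 745751L,    chrXI = 666816L,  chrXII = 1078177L,
  chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L
)

# GRCh38 primary assembled chromosomes (1-22, X, Y), bp
.HUMAN_GRCH38 <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415
)

#' ChromosomeSet: a karyotype with genome fractions
#'
#' Holds ordered chromosome names, lengths (bp), the derived genome
#' fractions \eqn{f_i = L_i / \sum_j L_j}, and the ploidy (copies per
#' chromosome, 1 or 2, optionally per chromosome). The fractions apportion a
#' genome-wide mismatch rate across chromosomes in the segregation
#' simulators.
#'
#' @slot chromNames ordered, unique chromosome identifiers.
#' @slot lengths positive chromosome lengths in base pairs.
#' @slot fractions per-chromosome fraction of the total genome length.
#' @slot ploidy integer copies per chromosome; length 1 or one per chromosome.
#'
#' @aliases ChromosomeSet
#' @export
setClass("ChromosomeSet",
  slots = c(
    chromNames = "character",
    lengths = "numeric",
    fractions = "numeric",
    ploidy = "integer"
  )
)

setValidity("ChromosomeSet", function(object) {
  msg <- character()
  n <- length(object@chromNames)
  if (n < 1L) msg <- c(msg, "at least one chromosome is required")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "chromosome names must be unique")
  if (length(object@lengths) != n || length(object@fractions) != n)
    msg <- c(msg, "lengths and fractions must match the number of chromosomes")
  if (any(!is.finite(object@lengths)) || any(object@lengths <= 0) || n < 1L)
    msg <- c(msg, "all chromosome lengths must be positive")
  else {
    if (abs(sum(object@fractions) - 1) > 1e-12)
      msg <- c(msg, "fractions must sum to 1")
    if (max(abs(object@fractions - object@lengths / sum(object@lengths))) > 1e-12)
      msg <- c(msg, "fractions must equal lengths / total length")
  }
  if (!length(object@ploidy) %in% c(1L, n) || any(!object@ploidy %in% 1:2))
    msg <- c(msg, "ploidy must be 1 or 2, scalar or one value per chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a ChromosomeSet
#'
#' @param names character vector of unique chromosome names.
#' @param lengths positive lengths in bp, same order as `names`.
#' @param ploidy copies per chromosome (1 = haploid, 2 = diploid); either a
#'   scalar or one value per chromosome.
#' @return A [ChromosomeSet-class] with fractions computed from the lengths.
#' @examples
#' ChromosomeSet(c("chrA", "chrB"), c(100, 300))
#' @export
ChromosomeSet <- function(names, lengths, ploidy = 2L) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  new("ChromosomeSet",
    chromNames = names,
    lengths = lengths,
    fractions = lengths / sum(lengths),
    ploidy = as.integer(ploidy)
  )
}

#' @rdname ChromosomeSet
#' @param object,x a `ChromosomeSet`.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname ChromosomeSet
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ChromosomeSet
#' @export
setGeneric("chromFractions", function(x) standardGeneric("chromFractions"))

#' @rdname ChromosomeSet
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname ChromosomeSet
#' @export
setMethod("chromNames", "ChromosomeSet", function(x) x@chromNames)

#' @rdname ChromosomeSet
#' @export
setMethod("chromLengths", "ChromosomeSet",
  function(x) stats::setNames(x@lengths, x@chromNames))

#' @rdname ChromosomeSet
#' @export
setMethod("chromFractions", "ChromosomeSet",
  function(x) stats::setNames(x@fractions, x@chromNames))

#' @rdname ChromosomeSet
#' @export
setMethod("ploidy", "ChromosomeSet", function(x) x@ploidy)

#' @rdname ChromosomeSet
#' @export
setMethod("length", "ChromosomeSet", function(x) length(x@chromNames))

setMethod("show", "ChromosomeSet", function(object) {
  cat("ChromosomeSet with", length(object), "chromosomes\n")
  cat("  total length:", format(sum(object@lengths), big.mark = ","), "bp\n")
  cat("  ploidy:", paste(unique(object@ploidy), collapse = "/"), "\n")
  head <- utils::head(object@chromNames, 5L)
  cat("  chromosomes:", paste(head, collapse = ", "),
      if (length(object) > 5L) "..." else "", "\n")
})

## ploidy expanded to one value per chromosome
.ploidyVec <- function(cs) {
  p <- cs@ploidy
  if (length(p) == 1L) rep(p, length(cs)) else p
}

## genome fractions repeated per chromosome copy, with the owning chromosome
## index as names-free attribute (used by the simulators)
.copyFractions <- function(cs) {
  p <- .ploidyVec(cs)
  list(
    fractions = rep(cs@fractions, times = p),
    chrom = rep(seq_along(cs@fractions), times = p)
  )
}

#' Built-in reference karyotypes
#'
#' Embedded full-assembly chromosome lengths for the budding-yeast S288C
#' reference (16 nuclear chromosomes, ~12.07 Mb) and the GRCh38 human
#' primary assembly (chr1-22, X, Y; ~3.09 Gb). Mitochondria and scaffolds
#' are excluded. Custom (e.g. repeat-masked) lengths can be supplied via
#' [loadChromosomeTable()].
#'
#' @param name `"yeast_s288c"` or `"human_grch38"`.
#' @param ploidy copies per chromosome; defaults to diploid.
#' @return A [ChromosomeSet-class].
#' @examples
#' builtinKaryotype("yeast_s288c")
#' @export
builtinKaryotype <- function(name = c("yeast_s288c", "human_grch38"),
                             ploidy = 2L) {
  if (!is.character(name) || !name[1L] %in% c("yeast_s288c", "human_grch38"))
    stop("unknown karyotype '", name[1L],
         "'; available: yeast_s288c, human_grch38")
  name <- match.arg(name)
  tab <- switch(name, yeast_s288c = .YEAST_S288C, human_grch38 = .HUMAN_GRCH38)
  ChromosomeSet(names(tab), tab, ploidy = ploidy)
}

#' Read a karyotype from a fai-style table
#'
#' Reads a tab-separated table whose first two columns are chromosome name
#' and length (a `samtools faidx` .fai file qualifies; extra columns are
#' ignored). Row order is preserved.
#'
#' @param path path to the TSV/fai file.
#' @param ploidy copies per chromosome.
#' @return A [ChromosomeSet-class].
#' @export
loadChromosomeTable <- function(path, ploidy = 2L) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) < 1L || ncol(tab) < 2L)
    stop("chromosome table must have at least one row and two columns")
  lens <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(lens) | lens <= 0 | lens != floor(lens)))
    stop("chromosome lengths must be positive integers")
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate chromosome names in table")
  ChromosomeSet(tab[[1L]], lens, ploidy = ploidy)
}

#' Write a karyotype as a fai-style table
#'
#' @param x a [ChromosomeSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChromosomeTable <- function(x, path) {
  stopifnot(is(x, "ChromosomeSet"))
  utils::write.table(
    data.frame(name = x@chromNames, length = format(x@lengths, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Seqinfo for GRanges construction
.seqinfo <- function(cs) {
  GenomeInfoDb::Seqinfo(seqnames = cs@chromNames,
                        seqlengths = as.integer(cs@lengths))
}
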