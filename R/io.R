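## Readers and writers for the file formats the pipeline touches:
## variant tables (minimal single-sample VCF subset, or TSV with
## chrom/pos/ref/alt), callable-region BED, fai-style karyotype tables,
## lineage manifests, and tidy TSV outputs. TSV is tab-delimited UTF-8
## with '.' decimals; output tables carry a '#'-prefixed provenance line.

#' Read variants from VCF or TSV
#'
#' VCF input is restricted to a minimal single-sample subset (CHROM, POS,
#' REF, ALT; INFO/FORMAT ignored); multi-allelic ALT entries are split.
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt`. Only
#' single-nucleotide variants are retained.
#'
#' @param path input file; `.vcf` extension selects VCF parsing.
#' @param chromset a [ChromosomeSet-class] providing the coordinate frame.
#' @return width-1 GRanges with `ref`/`alt` metadata columns.
#' @export
readVariants <- function(path, chromset) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    df <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("variant TSV must have columns ", paste(need, collapse = ", "))
  }
  ## split multi-allelic records, keep SNVs
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  df <- df[rep(seq_len(nrow(df)), lengths(alts)), , drop = FALSE]
  df$alt <- unlist(alts)
  df <- df[nchar(df$ref) == 1L & nchar(df$alt) == 1L, , drop = FALSE]
  bad <- setdiff(unique(df$chrom), chromNames(chromset))
  if (length(bad))
    stop("variants on chromosomes absent from the karyotype: ",
         paste(bad, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                               seqinfo = .seqinfo(chromset))
  S4Vectors::mcols(gr)$ref <- df$ref
  S4Vectors::mcols(gr)$alt <- df$alt
  sort(gr)
}

#' Write variants as TSV or minimal VCF
#'
#' @param gr width-1 GRanges with `ref`/`alt` metadata.
#' @param path output path; `.vcf` selects VCF.
#' @param sample sample name for the VCF header line.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(gr, path, sample = "sample") {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   pos = BiocGenerics::start(gr),
                   ref = S4Vectors::mcols(gr)$ref,
                   alt = S4Vectors::mcols(gr)$alt,
                   stringsAsFactors = FALSE)
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                     "QUAL", "FILTER", "INFO"),
                                   collapse = "\t"))), con)
    if (nrow(df))
      writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS", ".",
                       sep = "\t"), con)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read callable regions from BED
#'
#' BED is 0-based half-open on disk; the returned GRanges is 1-based.
#'
#' @param path BED file.
#' @param chromset a [ChromosomeSet-class].
#' @return GRanges of callable intervals.
#' @export
readCallable <- function(path, chromset) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- chromNames(chromset)
  GenomeInfoDb::seqinfo(gr) <- .seqinfo(chromset)
  GenomicRanges::reduce(gr)
}

#' Write callable regions as BED
#'
#' @param gr GRanges of intervals.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeCallable <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a lineage from a manifest
#'
#' The manifest is a TSV with columns `colony_id`, `division`, `position`
#' (D/GD1/GD2/GGD), `variants` and `callable` (paths, resolved relative to
#' the manifest's directory unless absolute).
#'
#' @param path manifest TSV.
#' @param chromset a [ChromosomeSet-class].
#' @return A [LineageTable-class].
#' @export
readLineageManifest <- function(path, chromset) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("colony_id", "division", "position", "variants", "callable")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  colonies <- lapply(seq_len(nrow(man)), function(i) {
    ColonyRecord(man$colony_id[i], man$division[i], man$position[i],
                 variants = readVariants(resolve(man$variants[i]), chromset),
                 callable = readCallable(resolve(man$callable[i]), chromset))
  })
  LineageTable(colonies, chromset)
}

#' Write a lineage (and optional ground truth) as a file set
#'
#' Emits per-colony variant files, per-colony BED callable files, a
#' `manifest.tsv`, a `karyotype.tsv`, and — when `sim` carries truth — a
#' `truth.tsv`, i.e. exactly the file set [readLineageManifest()] and the
#' calling pipeline consume.
#'
#' @param sim a [LineageTable-class] or the list returned by
#'   [generateLineage()].
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"vcf"` for the variant files.
#' @return path of the manifest, invisibly.
#' @export
writeLineageFiles <- function(sim, dir, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  lineage <- if (is(sim, "LineageTable")) sim else sim$lineage
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "vcf") "vcf" else "tsv"
  rows <- lapply(lineage@colonies, function(cc) {
    vf <- sprintf("%s.variants.%s", cc@colonyId, ext)
    bf <- sprintf("%s.callable.bed", cc@colonyId)
    writeVariants(cc@variants, file.path(dir, vf))
    writeCallable(cc@callable, file.path(dir, bf))
    data.frame(colony_id = cc@colonyId, division = cc@division,
               position = cc@position, variants = vf, callable = bf,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeChromosomeTable(lineage@chromset, file.path(dir, "karyotype.tsv"))
  if (!is(sim, "LineageTable") && !is.null(sim$truth))
    utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Write a tidy TSV with a provenance comment line
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed seed recorded in the comment line (optional).
#' @param config named character/list recorded in the comment line.
#' @return `path`, invisibly.
#' @export
writeTidyTSV <- function(df, path, seed = NULL, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sprintf("package=MutLineage/%s",
                    as.character(utils::packageVersion("MutLineage"))),
            if (!is.null(seed)) sprintf("seed=%s", seed),
            if (length(config)) paste(names(config), unlist(config),
                                      sep = "=", collapse = " "))
  writeLines(paste("#", paste(meta, collapse = " ")), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Write per-division segregant counts
#'
#' @param summary the data.frame from [segregantSummary()].
#' @param path output TSV.
#' @param seed optional seed for the provenance line.
#' @return `path`, invisibly.
#' @export
writeSegregantCounts <- function(summary, path, seed = NULL) {
  writeTidyTSV(summary, path, seed = seed)
}

#' Write per-chromosome segregant counts in long format
#'
#' @param counts list of [SegregantCounts-class].
#' @param path output TSV.
#' @param seed optional seed for the provenance line.
#' @return `path`, invisibly.
#' @export
writePerChromosomeCounts <- function(counts, path, seed = NULL) {
  rows <- lapply(counts, function(sc) {
    if (!sc@scorable) return(NULL)
    pc <- sc@perChromosome
    data.frame(division = sc@division,
               chrom = rep(rownames(pc), ncol(pc)),
               group = rep(colnames(pc), each = nrow(pc)),
               count = as.vector(pc), stringsAsFactors = FALSE)
  })
  writeTidyTSV(do.call(rbind, rows), path, seed = seed)
}
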