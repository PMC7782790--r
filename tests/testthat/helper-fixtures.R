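# Shared fixtures: tiny karyotypes and hand-built lineages with explicit
# variant placement, constructed in code at test time.

toyChromset <- function(ploidy = 2L) {
  ChromosomeSet(c("chrA", "chrB"), c(1000L, 3000L), ploidy = ploidy)
}

toySeqinfo <- function(cs) GenomeInfoDb::Seqinfo(chromNames(cs),
                                                 unname(chromLengths(cs)))

# variants from "chrom:pos:alt" keys
toyVariants <- function(keys, cs) {
  si <- toySeqinfo(cs)
  if (!length(keys))
    return(GenomicRanges::GRanges(seqinfo = si, ref = character(),
                                  alt = character()))
  parts <- strsplit(keys, ":", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    vapply(parts, `[[`, character(1), 1L),
    IRanges::IRanges(as.integer(vapply(parts, `[[`, character(1), 2L)),
                     width = 1L),
    seqinfo = si)
  S4Vectors::mcols(gr)$ref <- rep("A", length(gr))
  S4Vectors::mcols(gr)$alt <- vapply(parts, `[[`, character(1), 3L)
  gr
}

wholeGenomeCallable <- function(cs) {
  GenomicRanges::GRanges(chromNames(cs),
                         IRanges::IRanges(1L, unname(chromLengths(cs))),
                         seqinfo = toySeqinfo(cs))
}

# a pedigree where each colony's variant keys are given explicitly as a
# named list "m.position" -> character vector of keys
toyLineage <- function(keysByColony, nDivisions, cs = toyChromset(),
                       callable = NULL) {
  positions <- c("D", "GD1", "GD2", "GGD")
  if (is.null(callable)) callable <- wholeGenomeCallable(cs)
  colonies <- list()
  for (m in seq_len(nDivisions)) {
    for (p in positions) {
      nm <- sprintf("%d.%s", m, p)
      keys <- if (nm %in% names(keysByColony)) keysByColony[[nm]] else character()
      cal <- if (is.list(callable)) callable[[nm]] else callable
      colonies[[length(colonies) + 1L]] <-
        ColonyRecord(nm, m, p, toyVariants(keys, cs), cal)
    }
  }
  LineageTable(colonies, cs)
}

# place one variant key into the colonies that a given segregant group of
# a given division would carry (the inheritance rules of the pedigree)
groupCarrierColonies <- function(group, n, nDivisions) {
  switch(group,
    Da = sprintf("%d.%s", n, c("D", "GD2")),
    Db = sprintf("%d.%s", n, c("GD1", "GGD")),
    Ma = sprintf("%d.%s", n + 1L, c("D", "GD1", "GD2", "GGD")),
    Mb = as.vector(outer(seq(n + 2L, nDivisions), c("D", "GD1", "GD2", "GGD"),
                         function(m, p) sprintf("%d.%s", m, p))))
}

# build a lineage carrying one variant per requested (group, division)
toyLineageWithGroups <- function(spec, nDivisions, cs = toyChromset()) {
  keysByColony <- list()
  keyInfo <- list()
  pos <- 10L
  for (i in seq_len(nrow(spec))) {
    g <- spec$group[i]; n <- spec$division[i]
    key <- sprintf("chrB:%d:T", pos); pos <- pos + 7L
    for (cid in groupCarrierColonies(g, n, nDivisions))
      keysByColony[[cid]] <- c(keysByColony[[cid]], key)
    keyInfo[[i]] <- data.frame(key = key, group = g, division = n)
  }
  list(lineage = toyLineage(keysByColony, nDivisions, cs),
       truth = do.call(rbind, keyInfo))
}
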