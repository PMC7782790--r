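#' @importFrom methods new is validObject
#' @importFrom stats setNames
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL
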