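#' The 256 4-mer end motifs in lexicographic order
#'
#' Every end-motif profile in this package is a vector over these 256
#' motifs, ordered AAAA, AAAC, ..., TTTT (A < C < G < T). This ordering is
#' the index of the 256-point series that the decomposition module treats
#' as a signal.
#'
#' @return character vector of length 256.
#' @examples
#' head(all_motifs())
#' @export
all_motifs <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p4 = b, p3 = b, p2 = b, p1 = b,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest, so build motifs with the
  # last position fastest to get lexicographic order directly
  paste0(g$p1, g$p2, g$p3, g$p4)
}

# Reverse complement of an ACGT string (vectorised).
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}
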