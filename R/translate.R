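# Mitochondrial translation with explicit stop-codon reporting.
#
# The default genetic code is the invertebrate mitochondrial code (NCBI
# translation table 5), appropriate for metazoan COI; under it AGA/AGG
# encode serine and TGA tryptophan, so pseudogene screening with the
# standard code would miscount stops.

#' Translate DNA and report in-frame stop codons
#'
#' Translates complete codons of `seq` in the given frame under an NCBI
#' genetic code; a trailing partial codon is ignored. Codons containing an
#' ambiguous or non-ACGT base translate to `"X"` (never dropped).
#'
#' @param seq A single DNA string (IUPAC accepted; ambiguity yields X).
#' @param frame Integer 0, 1 or 2: number of bases skipped before the first
#'   codon.
#' @param code NCBI genetic code identifier as understood by
#'   [Biostrings::getGeneticCode()]; default `"5"`, the invertebrate
#'   mitochondrial code.
#' @return A list with `aa` (amino-acid string, stops as `*`) and `stops`
#'   (1-based codon indices of in-frame stop codons).
#' @examples
#' translate_dna("ATGAAA")$aa            # "MK"
#' translate_dna("AGA", code = "5")$aa   # "S" (serine, not stop)
#' @export
translate_dna <- function(seq, frame = 0L, code = "5") {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  seq <- normalize_iupac(seq)
  usable <- nchar(seq) - frame
  if (usable < 3L) stop("sequence too short to contain a codon in this frame")
  tab <- Biostrings::getGeneticCode(code)
  n_codon <- usable %/% 3L
  starts <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  list(aa = paste(aa, collapse = ""), stops = which(aa == "*"))
}

# stop-codon triplets of a genetic code (cached per call site; cheap)
.stop_codons <- function(code = "5") {
  tab <- Biostrings::getGeneticCode(code)
  names(tab)[tab == "*"]
}
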