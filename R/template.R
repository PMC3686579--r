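# Synthetic template realizing the published mini-barcode geometry.

#' Build a synthetic Folmer-region template
#'
#' A concrete template laying out the mini-barcode geometry: the LCO1490
#' priming site, followed by a 658 bp barcode region carrying one concrete
#' expansion member of mlCOIintF at barcode positions 320-345, followed by
#' the reverse-complemented jgHCO2198 priming site. In-silico PCR on this
#' template yields the two published amplicon geometries: a 313 bp insert
#' for mlCOIintF x jgHCO2198 (barcode positions 346-658) and a 319 bp
#' insert for LCO1490 x mlCOIintR (barcode positions 1-319).
#'
#' @param seed Integer seed for the random barcode background.
#' @return List with `template` (character), `barcode_start` (plus-strand
#'   position of barcode position 1) and `forward_site` (barcode
#'   coordinates of the planted mlCOIintF site).
#' @export
synth_folmer_template <- function(seed = 1L) {
  set.seed(seed)
  lco <- coi_primer("LCO1490")$sequence       # concrete, 25 nt
  f_member <- sample(expand_primer(coi_primer("mlCOIintF")), 1L)
  h_member <- sample(expand_primer(coi_primer("jgHCO2198")), 1L)
  barcode <- sample(c("A", "C", "G", "T"), 658L, replace = TRUE)
  barcode <- paste(barcode, collapse = "")
  substr(barcode, 320L, 345L) <- f_member
  list(template = paste0(lco, barcode, reverse_complement(h_member)),
       barcode_start = nchar(lco) + 1L,
       forward_site = c(320L, 345L))
}
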