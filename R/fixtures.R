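# Shipped oligo fixtures: the ten published COI primers, the three
# predator blocking primers, and the five 6-bp sample tags.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "minicoi")
  if (!nzchar(path)) stop("fixture not found: ", file)
  path
}

#' Published COI primers shipped with the package
#'
#' The ten primers used throughout: the classic Folmer pair
#' (LCO1490/HCO2198), their degenerate (dg) and inosine (jg) versions, the
#' Uni-Minibar pair, and the mlCOIintF/mlCOIintR mini-barcode pair designed
#' from the conserved site at positions 320-345 of the 658 bp barcode.
#'
#' @return A data frame with columns `name`, `sequence`, `orientation`,
#'   `three_prime_block`.
#' @seealso [coi_primer()] for a single primer as a `degenerate_primer`.
#' @export
coi_primers <- function() {
  read.delim(.extdata("coi_primers.tsv"), colClasses = c(
    name = "character", sequence = "character",
    orientation = "character", three_prime_block = "logical"))
}

#' Fetch one shipped primer as a `degenerate_primer`
#'
#' @param name Primer name as listed by [coi_primers()].
#' @return A `degenerate_primer`.
#' @examples
#' degeneracy(coi_primer("mlCOIintR"))  # 128
#' @export
coi_primer <- function(name) {
  tab <- coi_primers()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown primer: ", name,
                     " (see coi_primers()$name)")
  degenerate_primer(tab$sequence[i], name = tab$name[i],
                    orientation = tab$orientation[i],
                    three_prime_block = tab$three_prime_block[i])
}

#' Predator-specific blocking primers shipped with the package
#'
#' Three 29-nt 3'-blocked (Spacer-C3) oligos that overlap the reverse
#' universal priming site and extend into predator-specific sequence, one
#' per predatory fish species.
#'
#' @return A data frame with columns `name`, `predator_species`,
#'   `sequence`, `three_prime_block`.
#' @export
coi_blocking_primers <- function() {
  read.delim(.extdata("blocking_primers.tsv"), colClasses = c(
    name = "character", predator_species = "character",
    sequence = "character", three_prime_block = "logical"))
}

#' Sample multiplexing tags shipped with the package
#'
#' The five 6-bp tags (T1-T5) attached to the 5' end of both tailed
#' primers for hierarchical sample multiplexing.
#'
#' @return A data frame with columns `tag_id`, `tag`.
#' @export
coi_sample_tags <- function() {
  read.delim(.extdata("sample_tags.tsv"),
             colClasses = c(tag_id = "character", tag = "character"))
}
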