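# Degenerate-oligo model: the unit of all primer arithmetic.

#' Construct a degenerate primer
#'
#' An IUPAC-coded oligo with an orientation and an optional non-extendable
#' 3' end (Spacer-C3 style, as used for blocking primers).
#'
#' @param sequence IUPAC string, written 5' to 3'.
#' @param name Label for reports.
#' @param orientation `"forward"` or `"reverse"`. A reverse primer anneals to
#'   the minus strand, i.e. its binding footprint on the plus strand is the
#'   reverse complement of `sequence`.
#' @param three_prime_block Logical; `TRUE` for 3'-blocked (non-extendable)
#'   oligos such as predator blocking primers.
#' @return An object of class `degenerate_primer`.
#' @examples
#' p <- degenerate_primer("GGWACWGGWTGAACWGTWTAYCCYCC", name = "mlCOIintF")
#' degeneracy(p)
#' @export
degenerate_primer <- function(sequence, name = "primer",
                              orientation = c("forward", "reverse"),
                              three_prime_block = FALSE) {
  orientation <- match.arg(orientation)
  sequence <- normalize_iupac(sequence)
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         three_prime_block = isTRUE(three_prime_block)),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s%s)\n  5'-%s-3'  length %d, degeneracy %d, %d degenerate site(s)\n",
              x$name, x$orientation,
              if (x$three_prime_block) ", 3'-blocked" else "",
              x$sequence, nchar(x$sequence), degeneracy(x),
              count_degenerate_positions(x)))
  invisible(x)
}

.primer_seq <- function(primer) {
  if (inherits(primer, "degenerate_primer")) primer$sequence
  else normalize_iupac(primer)
}

.primer_sets <- function(primer) {
  ch <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1L]]
  .IUPAC_SETS[ch]
}

#' Fold degeneracy of a degenerate primer
#'
#' Product over positions of the number of bases each IUPAC symbol denotes.
#' Inosine contributes a factor of 1: it is a single physical base, so it
#' does not multiply the number of distinct oligos in the synthesis mix
#' (contrast [expand_primer()], where inosine expands to all four bases).
#'
#' @param primer A `degenerate_primer` or IUPAC string.
#' @return A positive integer (as double, to allow large products).
#' @examples
#' degeneracy("GGRGGRTASACSGTTCASCCSGTSCC")  # 128
#' @export
degeneracy <- function(primer) {
  ch <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1L]]
  sizes <- lengths(.IUPAC_SETS[ch])
  sizes[ch == "I"] <- 1L
  prod(sizes)
}

#' Number of degenerate positions in a primer
#'
#' Counts positions whose IUPAC symbol denotes more than one base; inosine
#' is excluded (it is one base, not a mixture).
#'
#' @inheritParams degeneracy
#' @return Non-negative integer.
#' @examples
#' count_degenerate_positions("GGWACWGGWTGAACWGTWTAYCCYCC")  # 7
#' @export
count_degenerate_positions <- function(primer) {
  ch <- strsplit(.primer_seq(primer), "", fixed = TRUE)[[1L]]
  sizes <- lengths(.IUPAC_SETS[ch])
  sum(sizes > 1L & ch != "I")
}

#' Expand a degenerate primer to its concrete sequences
#'
#' All concrete ACGT sequences consistent with the IUPAC string. Inosine is
#' expanded to all four bases here, so for primers containing inosine the
#' expansion is larger than [degeneracy()].
#'
#' @inheritParams degeneracy
#' @param cap Maximum allowed expansion size; larger requests are refused
#'   to prevent combinatorial blow-up.
#' @return Character vector of concrete sequences, lexicographically sorted.
#' @examples
#' expand_primer("AY")  # "AC" "AT"
#' @export
expand_primer <- function(primer, cap = 65536L) {
  sets <- .primer_sets(primer)
  n <- prod(lengths(sets))
  if (n > cap) {
    stop(sprintf("expansion size %.0f exceeds cap %d; raise `cap` deliberately if intended",
                 n, cap))
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}
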