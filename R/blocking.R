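# Predator-specific blocking primer design.
#
# A blocking primer overlaps the 3' end of a universal priming site and
# extends into sequence specific to the predator; synthesized with a
# 3' Spacer-C3 it anneals but cannot be extended, suppressing predator
# amplification. A candidate is only acceptable if every prey reference
# differs from the predator in the extension region by at least a minimum
# number of mismatches, so prey amplification is not blocked.

#' Design a predator-specific blocking primer
#'
#' Builds the candidate that overlaps the universal primer's 3' end by
#' `overlap_len` bases and extends `total_len - overlap_len` bases into
#' the adjacent predator-specific sequence, then screens the extension
#' region against every prey reference. Prey references must be
#' positionally homologous with `predator_ref` (same coordinate system,
#' no gaps).
#'
#' @param predator_ref Concrete predator template (plus strand).
#' @param universal_site A binding site of the universal primer on
#'   `predator_ref`: one row of [find_binding_sites()] output, or any
#'   list with `strand`, `start`, `end`.
#' @param overlap_len Bases shared with the universal priming site
#'   (counted from its 3' end).
#' @param total_len Total blocker length; must exceed `overlap_len`.
#' @param prey_refs Named character vector of prey references.
#' @param min_prey_mismatches Minimum mismatches every prey must show in
#'   the extension region (default 4); otherwise the candidate is
#'   rejected with the closest prey named.
#' @return An object of class `blocking_primer`: list with `sequence`
#'   (5' to 3'), `strand`, `overlap_span` and `extension_span`
#'   (plus-strand coordinates), `three_prime_block = TRUE` and
#'   `prey_mismatches`.
#' @export
design_blocking_primer <- function(predator_ref, universal_site,
                                   overlap_len, total_len, prey_refs,
                                   min_prey_mismatches = 4L) {
  predator_ref <- normalize_iupac(predator_ref)
  stopifnot(overlap_len >= 1L, overlap_len < total_len)
  strand <- universal_site$strand[1L]
  ext_len <- total_len - overlap_len
  if (strand == "+") {
    e <- universal_site$end[1L]
    span <- c(e - overlap_len + 1L, e + ext_len)
    ext <- c(e + 1L, e + ext_len)
    over <- c(e - overlap_len + 1L, e)
  } else {
    s <- universal_site$start[1L]
    span <- c(s - ext_len, s + overlap_len - 1L)
    ext <- c(s - ext_len, s - 1L)
    over <- c(s, s + overlap_len - 1L)
  }
  if (span[1L] < 1L || span[2L] > nchar(predator_ref))
    stop("blocker footprint extends beyond the template")
  region <- substr(predator_ref, span[1L], span[2L])
  seq5to3 <- if (strand == "+") region else reverse_complement(region)

  prey_refs <- vapply(prey_refs, normalize_iupac, "")
  if (is.null(names(prey_refs)))
    names(prey_refs) <- sprintf("prey_%d", seq_along(prey_refs))
  pred_ext <- substr(predator_ref, ext[1L], ext[2L])
  mm <- vapply(prey_refs, function(p) {
    if (nchar(p) < ext[2L]) return(NA_integer_)
    count_mismatches(pred_ext, substr(p, ext[1L], ext[2L]))$count
  }, integer(1))
  if (anyNA(mm))
    stop("prey reference(s) shorter than the extension region: ",
         paste(names(mm)[is.na(mm)], collapse = ", "))
  if (any(mm < min_prey_mismatches)) {
    worst <- names(mm)[which.min(mm)]
    stop("no qualifying blocker: prey '", worst, "' has only ", min(mm),
         " mismatch(es) in the extension region (need >= ",
         min_prey_mismatches, ")")
  }
  structure(list(sequence = seq5to3, strand = strand,
                 overlap_span = over, extension_span = ext,
                 three_prime_block = TRUE, prey_mismatches = mm),
            class = "blocking_primer")
}

#' @export
print.blocking_primer <- function(x, ...) {
  cat(sprintf("<blocking_primer> 5'-%s-3' (%s strand, 3'-blocked)\n  overlap %d-%d, extension %d-%d; min prey mismatches %d\n",
              x$sequence, x$strand, x$overlap_span[1L], x$overlap_span[2L],
              x$extension_span[1L], x$extension_span[2L],
              min(x$prey_mismatches)))
  invisible(x)
}
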