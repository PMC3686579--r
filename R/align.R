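# Alignment helpers shared by read_qc and otu_pipeline.
#
# Scoring follows the package defaults stated in output metadata:
# match +1, mismatch -2, gap run of length L costs 10 + L (affine,
# opening 10, extension 1).

.ALN_DEFAULTS <- list(match = 1, mismatch = -2, gap_open = 10, gap_ext = 1)

# coerce to a named character vector of sequences (as.character drops
# names, so they are carried over explicitly)
.named_seqs <- function(x, prefix = "read") {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- if (is.null(nm)) sprintf("%s_%d", prefix, seq_along(x)) else nm
  x
}

# Batch-align reads against one reference. type "global-local" aligns the
# whole read against a free-ended reference; "global" is end-to-end.
.align_batch <- function(reads, ref, type = c("global-local", "global"),
                         par = .ALN_DEFAULTS) {
  type <- match.arg(type)
  .cpp_align_batch(as.character(reads), as.character(ref),
                   par$match, par$mismatch, par$gap_open, par$gap_ext,
                   type == "global-local")
}

# identity = matches / alignment columns; with exclude_end_gaps the
# leading/trailing columns where either row is gapped are dropped from the
# denominator (internal gap columns still count).
.aln_identity <- function(ap, as_, exclude_end_gaps = TRUE) {
  mapply(function(p, s) {
    pc <- strsplit(p, "", fixed = TRUE)[[1L]]
    sc <- strsplit(s, "", fixed = TRUE)[[1L]]
    both <- which(pc != "-" & sc != "-")
    if (!length(both)) return(0)
    span <- if (exclude_end_gaps) both[1L]:both[length(both)]
            else seq_along(pc)
    sum(pc[span] == sc[span] & pc[span] != "-") / length(span)
  }, ap, as_, USE.NAMES = FALSE)
}

#' Pairwise identity of a query against reference sequences
#'
#' Global (end-to-end) affine-gap alignment; identity is matches divided by
#' alignment columns with end-gap columns excluded. This is the identity
#' convention used for OTU clustering radii and taxonomy thresholds
#' throughout the package.
#'
#' @param query A single sequence.
#' @param refs Character vector (or `DNAStringSet`) of references.
#' @return Numeric vector of identities in `[0, 1]`, one per reference.
#' @export
pairwise_identity <- function(query, refs) {
  refs <- as.character(refs)
  if (!length(refs)) return(numeric(0))
  a <- .align_batch(refs, query, type = "global")
  .aln_identity(a$pattern, a$subject)
}

# index of the reference sharing the most k-mers with each read
.best_ref_index <- function(reads, refs, k = 8L) {
  .cpp_best_ref_kmer(as.character(reads), as.character(refs), as.integer(k))
}
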