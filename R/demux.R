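# Hierarchical demultiplexing of tagged amplicon reads.
#
# Expected read layout (5' to 3' on the sequenced strand):
#   [MID][6-bp tag][forward primer][insert][revcomp(reverse primer)][revcomp(tag)]
# The MID identifies the library pool, the tag the sample within the pool.
# Tag/MID matching is exact; only the primer regions tolerate mismatches
# (default ceiling 2, reads beyond it are discarded).

#' Demultiplex tagged amplicon reads
#'
#' Assigns each read to a sample by exact MID+tag prefix match, verifies
#' both primer regions against their degenerate primers, trims to the
#' insert and applies a minimum-length floor. Every read receives exactly
#' one verdict (`pass`, `unassigned`, `discard_primer` or
#' `discard_length`), so the output partitions the input.
#'
#' @param reads Named character vector or `DNAStringSet` of raw reads.
#' @param scheme Data frame with columns `sample_id`, `mid`, `tag`
#'   (concrete DNA; `mid` may be `""` for un-pooled designs).
#' @param forward,reverse The tailed amplification primers
#'   (`degenerate_primer` or IUPAC string).
#' @param max_primer_mismatches Per-primer mismatch ceiling (default 2;
#'   reads with more are discarded).
#' @param min_length Minimum trimmed insert length (default 150 nt), the
#'   base-space counterpart of a pyrosequencing flow-count floor.
#' @return List with `records` (one row per read: assignment, per-primer
#'   mismatches, insert length, verdict, insert sequence) and `samples`
#'   (named list of passing insert vectors per sample).
#' @export
demultiplex <- function(reads, scheme, forward, reverse,
                        max_primer_mismatches = 2L, min_length = 150L) {
  reads <- .named_seqs(reads)
  stopifnot(is.data.frame(scheme),
            all(c("sample_id", "mid", "tag") %in% names(scheme)))
  if (anyDuplicated(scheme$sample_id))
    stop("duplicate sample_id in tag scheme")
  key <- paste0(toupper(scheme$mid), toupper(scheme$tag))
  if (anyDuplicated(key))
    stop("duplicate (mid, tag) combination in tag scheme")
  # non-degenerate requirement: no key may be a prefix of another
  for (i in seq_along(key)) {
    pre <- startsWith(key, key[i]) & seq_along(key) != i
    if (any(pre)) stop("tag scheme is degenerate: key for sample '",
                       scheme$sample_id[i], "' is a prefix of another")
  }
  fseq <- .primer_seq(forward); Lf <- nchar(fseq)
  rseq <- .primer_seq(reverse); Lr <- nchar(rseq)
  tag_len <- nchar(scheme$tag)

  n <- length(reads)
  sample_id <- rep(NA_character_, n)
  mm_f <- mm_r <- rep(NA_integer_, n)
  insert <- rep(NA_character_, n)
  verdict <- rep("unassigned", n)

  which_key <- rep(NA_integer_, n)
  for (i in seq_along(key)) {
    hit <- is.na(which_key) & startsWith(reads, key[i])
    which_key[hit] <- i
  }
  for (i in seq_along(key)) {
    idx <- which(which_key == i)
    if (!length(idx)) next
    sample_id[idx] <- scheme$sample_id[i]
    off <- nchar(key[i])
    tl <- tag_len[i]
    for (j in idx) {
      rd <- reads[[j]]
      nlen <- nchar(rd)
      # need room for both primers and the 3' tag copy
      if (nlen < off + Lf + Lr + tl) { verdict[j] <- "discard_length"; next }
      f_site <- substr(rd, off + 1L, off + Lf)
      r_region <- substr(rd, nlen - tl - Lr + 1L, nlen - tl)
      mm_f[j] <- count_mismatches(fseq, f_site)$count
      mm_r[j] <- count_mismatches(rseq, reverse_complement(r_region))$count
      if (mm_f[j] > max_primer_mismatches ||
          mm_r[j] > max_primer_mismatches) {
        verdict[j] <- "discard_primer"
        next
      }
      ins <- substr(rd, off + Lf + 1L, nlen - tl - Lr)
      if (nchar(ins) < min_length) { verdict[j] <- "discard_length"; next }
      insert[j] <- ins
      verdict[j] <- "pass"
    }
  }
  records <- data.frame(
    read_id = names(reads), sample_id = sample_id,
    primer_mismatch_fwd = mm_f, primer_mismatch_rev = mm_r,
    insert_length = ifelse(is.na(insert), NA_integer_, nchar(insert)),
    verdict = verdict, insert = insert, row.names = NULL)
  keep <- records$verdict == "pass"
  samples <- split(stats::setNames(records$insert[keep],
                                   records$read_id[keep]),
                   records$sample_id[keep])
  list(records = records, samples = samples)
}
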