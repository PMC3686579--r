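# Reading-frame-aware functional filtering.
#
# Each read is aligned (affine-gap, reference ends free) to its closest
# in-frame reference; the reading frame is inherited through the
# alignment. Gap runs whose length is a multiple of 3 are whole-codon
# insertions/deletions; any other gap run is a frameshift. Stop codons are
# counted on the frame-corrected read. Reads with exactly one frameshift
# and no other anomaly are repaired by removing the affected codon
# entirely (its position within the codon cannot be known).

# per-alignment classification; returns a list of counters + repair data
.classify_one <- function(pat, sub, sub_start, code_stops) {
  pc <- strsplit(pat, "", fixed = TRUE)[[1L]]
  sc <- strsplit(sub, "", fixed = TRUE)[[1L]]
  ncol_ <- length(pc)
  sub_pos <- cumsum(sc != "-")
  sub_pos[sc == "-"] <- NA_integer_
  sub_pos <- sub_pos + sub_start - 1L
  codon_of <- (sub_pos - 1L) %/% 3L + 1L   # reference codon per column

  # gap runs
  runs <- function(is_gap) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep],
               len = r$lengths[keep])
  }
  del_runs <- runs(pc == "-")          # gap in read: deletion
  ins_runs <- runs(sc == "-")          # gap in reference: insertion
  n_del_codons <- sum(del_runs$len %/% 3L)
  n_ins_codons <- sum(ins_runs$len %/% 3L)
  fs_del <- del_runs[del_runs$len %% 3L != 0L, , drop = FALSE]
  fs_ins <- ins_runs[ins_runs$len %% 3L != 0L, , drop = FALSE]
  n_fs <- nrow(fs_del) + nrow(fs_ins)
  # a 4-base run counts as one frameshift plus one whole codon (len %/% 3)

  # frame-corrected stop count: complete read triplets on the ref codon grid
  cod_tab <- split(seq_len(ncol_)[!is.na(codon_of)],
                   codon_of[!is.na(codon_of)])
  complete <- vapply(cod_tab, function(cols)
    length(cols) == 3L && all(pc[cols] != "-"), TRUE)
  triplets <- vapply(cod_tab[complete], function(cols)
    paste(pc[cols], collapse = ""), character(1))
  n_stops <- sum(triplets %in% code_stops)

  # repair candidate: exactly one frameshift run, nothing else
  repaired <- NA_character_
  if (n_fs == 1L && n_ins_codons == 0L && n_del_codons == 0L &&
      n_stops == 0L) {
    if (nrow(fs_del) == 1L) {
      # deletion run: the codon(s) it touches are incomplete and drop out
      # via the completeness filter below
      affected <- unique(codon_of[fs_del$start:fs_del$end])
    } else {
      # inserted bases lie between reference positions: attach to the
      # codon on the 3' side (or 5' side at the alignment end)
      nxt <- which(!is.na(codon_of) & seq_len(ncol_) > fs_ins$end)
      affected <- if (length(nxt)) codon_of[nxt[1L]] else {
        prv <- which(!is.na(codon_of) & seq_len(ncol_) < fs_ins$start)
        codon_of[prv[length(prv)]]
      }
    }
    # output = complete reference codons minus the affected one(s);
    # insertion columns have no reference codon and drop out too
    keep_codons <- setdiff(as.integer(names(cod_tab))[complete], affected)
    keep_cols <- !is.na(codon_of) & codon_of %in% keep_codons
    repaired <- paste(pc[keep_cols], collapse = "")
  }

  list(n_stops = n_stops, n_fs = n_fs, n_ins = n_ins_codons,
       n_del = n_del_codons, repaired = repaired)
}

#' Classify reads against in-frame references
#'
#' Aligns each read to its closest reference (shared-k-mer prescreen, then
#' affine-gap alignment with free reference ends) and classifies open
#' reading frame interruptions: substitution stop codons, frameshifting
#' gap runs (length not a multiple of 3), and whole-codon insertions or
#' deletions. Reads without a reference above the identity floor are
#' flagged unalignable.
#'
#' @param reads Named character vector (or `DNAStringSet`) of trimmed
#'   inserts.
#' @param references Named character vector (or `DNAStringSet`) of
#'   in-frame, stop-free references; lengths must be multiples of 3.
#' @param code NCBI genetic code id (default "5", invertebrate
#'   mitochondrial).
#' @param min_identity Identity floor below which a read is unalignable.
#' @return Data frame with one row per read: `read_id`, `ref_id`,
#'   `identity`, `n_stop_codons`, `n_frameshifts`, `n_inserted_codons`,
#'   `n_deleted_codons`, `alignable`, `sequence`, and `repaired_seq`
#'   (the codon-trimmed repair for single-frameshift reads, else `NA`).
#' @seealso [apply_keep_rules()] for the verdicts.
#' @export
frame_classify <- function(reads, references, code = "5",
                           min_identity = 0.5) {
  reads <- .named_seqs(reads)
  refs <- .named_seqs(references, prefix = "ref")
  if (any(nchar(refs) %% 3L != 0L))
    stop("references must have length a multiple of 3 (frame 0)")
  stops <- .stop_codons(code)
  for (r in seq_along(refs))
    if (length(translate_dna(refs[[r]], 0L, code)$stops))
      stop("reference '", names(refs)[r], "' contains in-frame stop codons")

  best <- .best_ref_index(reads, refs)
  out <- vector("list", length(reads))
  for (r in unique(best)) {
    idx <- which(best == r)
    a <- .align_batch(reads[idx], refs[[r]], type = "global-local")
    ident <- .aln_identity(a$pattern, a$subject, exclude_end_gaps = FALSE)
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (ident[k] < min_identity) {
        out[[j]] <- data.frame(
          read_id = names(reads)[j], ref_id = names(refs)[r],
          identity = ident[k], n_stop_codons = NA_integer_,
          n_frameshifts = NA_integer_, n_inserted_codons = NA_integer_,
          n_deleted_codons = NA_integer_, alignable = FALSE,
          sequence = reads[[j]], repaired_seq = NA_character_)
        next
      }
      cl <- .classify_one(a$pattern[k], a$subject[k], a$subject_start[k],
                          stops)
      out[[j]] <- data.frame(
        read_id = names(reads)[j], ref_id = names(refs)[r],
        identity = ident[k], n_stop_codons = cl$n_stops,
        n_frameshifts = cl$n_fs, n_inserted_codons = cl$n_ins,
        n_deleted_codons = cl$n_del, alignable = TRUE,
        sequence = reads[[j]], repaired_seq = cl$repaired)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the functional keep rules to classified reads
#'
#' A read passes with no stop codons, no frameshifts, no inserted codons
#' and fewer than `max_deletions` deleted codons. A read with exactly one
#' frameshift and no other anomaly is kept as `repaired`, with the codon
#' containing the frameshifted position removed entirely (the repaired
#' output is codon-trimmed, so its length is a multiple of 3). Any other
#' read is discarded under the first violated rule in the fixed order
#' stop > frameshift > insertion > deletion; unalignable reads are
#' `unassigned`.
#'
#' @param records Output of [frame_classify()].
#' @param max_deletions Discard reads with at least this many deleted
#'   codons (default 4: up to three deleted codons are tolerated).
#' @return `records` with `verdict` and `output_sequence` columns added;
#'   `output_sequence` is the insert for passing reads, the repaired
#'   sequence for repaired reads, `NA` otherwise.
#' @export
apply_keep_rules <- function(records, max_deletions = 4L) {
  st <- records$n_stop_codons
  fs <- records$n_frameshifts
  ins <- records$n_inserted_codons
  del <- records$n_deleted_codons
  verdict <- rep(NA_character_, nrow(records))
  verdict[!records$alignable] <- "unassigned"
  ok <- records$alignable
  is_pass <- ok & st == 0L & fs == 0L & ins == 0L & del < max_deletions
  is_rep <- ok & st == 0L & fs == 1L & ins == 0L & del == 0L
  verdict[is_pass] <- "pass"
  verdict[is_rep] <- "repaired"
  rest <- ok & !is_pass & !is_rep
  verdict[rest & st > 0L] <- "discard_stop"
  verdict[rest & st == 0L & fs > 0L] <- "discard_frameshift"
  verdict[rest & st == 0L & fs == 0L & ins > 0L] <- "discard_insertion"
  verdict[rest & st == 0L & fs == 0L & ins == 0L] <- "discard_deletion"
  records$verdict <- verdict
  records$output_sequence <- ifelse(
    verdict == "pass", records$sequence,
    ifelse(verdict == "repaired", records$repaired_seq, NA_character_))
  records
}
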