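# End-to-end read QC: demultiplex -> primer/length filter -> reading-frame
# filter with repair -> chimera screen.

#' Run the full read-QC pipeline
#'
#' Chains [demultiplex()], [frame_classify()] + [apply_keep_rules()] and
#' [detect_chimera()] and produces one verdict per input read plus the
#' per-sample sets of retained (passing or repaired) inserts. Chimeric
#' reads that survived the frame filter are re-verdicted
#' `discard_chimera`.
#'
#' @inheritParams demultiplex
#' @param references In-frame, stop-free references for
#'   [frame_classify()] (also the chimera parent panel).
#' @param code NCBI genetic code id (default "5").
#' @param max_deletions See [apply_keep_rules()].
#' @param chimera_references Parent panel for the chimera screen; defaults
#'   to `references`. One representative per species is sufficient and
#'   proportionally faster.
#' @param chimera_min_gain,chimera_min_segment See [detect_chimera()].
#' @return List with `records` (every input read: sample, counters,
#'   verdict, output sequence), `summary` (named counts: input, per
#'   verdict, final retained) and `samples` (per-sample named vectors of
#'   retained sequences).
#' @export
run_read_qc <- function(reads, scheme, forward, reverse, references,
                        code = "5", max_primer_mismatches = 2L,
                        min_length = 150L, max_deletions = 4L,
                        chimera_references = references,
                        chimera_min_gain = 0.02,
                        chimera_min_segment = 30L) {
  dm <- demultiplex(reads, scheme, forward, reverse,
                    max_primer_mismatches = max_primer_mismatches,
                    min_length = min_length)
  rec <- dm$records
  rec$n_stop_codons <- rec$n_frameshifts <- rec$n_inserted_codons <-
    rec$n_deleted_codons <- NA_integer_
  rec$output_sequence <- NA_character_

  ok <- rec$verdict == "pass"
  if (any(ok)) {
    fc <- frame_classify(stats::setNames(rec$insert[ok], rec$read_id[ok]),
                         references, code = code)
    fc <- apply_keep_rules(fc, max_deletions = max_deletions)
    m <- match(rec$read_id[ok], fc$read_id)
    rec$verdict[ok] <- fc$verdict[m]
    rec$n_stop_codons[ok] <- fc$n_stop_codons[m]
    rec$n_frameshifts[ok] <- fc$n_frameshifts[m]
    rec$n_inserted_codons[ok] <- fc$n_inserted_codons[m]
    rec$n_deleted_codons[ok] <- fc$n_deleted_codons[m]
    rec$output_sequence[ok] <- fc$output_sequence[m]
  }

  kept <- rec$verdict %in% c("pass", "repaired")
  if (any(kept)) {
    ch <- detect_chimera(stats::setNames(rec$output_sequence[kept],
                                         rec$read_id[kept]),
                         chimera_references,
                         min_score_gain = chimera_min_gain,
                         min_segment = chimera_min_segment)
    flag <- ch$read_id[ch$is_chimera]
    hit <- rec$read_id %in% flag
    rec$verdict[hit] <- "discard_chimera"
    rec$output_sequence[hit] <- NA_character_
  }

  final <- rec$verdict %in% c("pass", "repaired")
  verdicts <- c("pass", "repaired", "discard_chimera", "discard_stop",
                "discard_frameshift", "discard_insertion",
                "discard_deletion", "discard_primer", "discard_length",
                "unassigned")
  summary <- c(input = nrow(rec),
               stats::setNames(as.integer(table(factor(rec$verdict,
                 levels = verdicts))), verdicts),
               final = sum(final))
  samples <- split(stats::setNames(rec$output_sequence[final],
                                   rec$read_id[final]),
                   rec$sample_id[final])
  list(records = rec, summary = as.list(summary), samples = samples)
}

#' Write a read-QC summary as JSON
#'
#' @param qc Result of [run_read_qc()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(qc, path) {
  jsonlite::write_json(qc$summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
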