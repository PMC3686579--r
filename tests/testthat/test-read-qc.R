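# Demultiplexing, frame classification with repair, keep rules, chimera
# screen.

# a minimal single-sample layout: no MID, 6-bp tag, concrete primers
mini_scheme <- data.frame(sample_id = "S1", mid = "", tag = "AGCACG")
FWD <- degenerate_primer("ACGTWCGTACGTACGTACGT", name = "fwd")
REV <- degenerate_primer("TTGCAYGCAATGCAATGCAA", name = "rev",
                         orientation = "reverse")
FM <- expand_primer(FWD)[1]
RM <- expand_primer(REV)[1]

build_read <- function(insert, tag = "AGCACG", fwd = FM, rev = RM) {
  paste0(tag, fwd, insert, reverse_complement(rev),
         reverse_complement(tag))
}

test_that("demultiplexing assigns by exact tag and enforces the primer ceiling", {
  set.seed(20)
  ins <- rand_dna(180)
  reads <- c(
    good = build_read(ins),
    two_mm = build_read(ins, fwd = mutate_seq(FM, 2, seed = 21)),
    three_mm = build_read(ins, fwd = mutate_seq(FM, 3, seed = 22)),
    bad_tag = build_read(ins, tag = "TTTTTT"),
    short = build_read(rand_dna(100)))
  dm <- demultiplex(reads, mini_scheme, FWD, REV, min_length = 150)
  v <- setNames(dm$records$verdict, dm$records$read_id)
  expect_equal(v[["good"]], "pass")
  expect_equal(v[["two_mm"]], "pass")        # boundary: 2 mismatches kept
  expect_equal(v[["three_mm"]], "discard_primer")
  expect_equal(v[["bad_tag"]], "unassigned")
  expect_equal(v[["short"]], "discard_length")
  expect_equal(dm$records$primer_mismatch_fwd[1], 0)
  expect_equal(dm$records$primer_mismatch_fwd[2], 2)
  # partition: every read gets exactly one verdict; counts conserved
  expect_equal(nrow(dm$records), length(reads))
  expect_setequal(dm$records$read_id, names(reads))
  expect_equal(sum(lengths(dm$samples)), sum(v == "pass"))
  # trimmed insert excludes tags and primers
  expect_equal(unname(dm$samples$S1[["good"]]), ins)
})

test_that("degenerate tag schemes and duplicate samples are rejected", {
  expect_error(demultiplex("ACGT", data.frame(sample_id = c("A", "A"),
                                              mid = "", tag = c("AAAAAA", "CCCCCC")),
                           FWD, REV), "duplicate sample_id")
  expect_error(demultiplex("ACGT", data.frame(sample_id = c("A", "B"),
                                              mid = c("", ""), tag = c("AAAAAA", "AAAAAA")),
                           FWD, REV), "duplicate")
})

test_that("frame classification counts stops, frameshifts and codon indels", {
  set.seed(23)
  panel <- small_panel()
  refs <- panel$qc_references
  ref <- refs[[1]]
  reads <- c(
    clean = ref,
    one_extra = paste0(substr(ref, 1, 150), "A", substr(ref, 151, nchar(ref))),
    one_missing = paste0(substr(ref, 1, 150), substr(ref, 152, nchar(ref))),
    codon_del = paste0(substr(ref, 1, 150), substr(ref, 154, nchar(ref))),
    stop_mut = `substr<-`(ref, 91, 93, "TAA"))
  fc <- frame_classify(reads, refs)
  fc <- fc[match(names(reads), fc$read_id), ]
  expect_equal(fc$n_frameshifts, c(0, 1, 1, 0, 0))
  expect_equal(fc$n_deleted_codons, c(0, 0, 0, 1, 0))
  expect_equal(fc$n_inserted_codons, c(0, 0, 0, 0, 0))
  expect_equal(fc$n_stop_codons, c(0, 0, 0, 0, 1))
  expect_true(all(fc$alignable))
  # junk sequence falls below the identity floor
  junk <- frame_classify(c(x = strrep("ACGT", 80)), refs)
  expect_false(junk$alignable)
})

test_that("keep rules honor the deletion boundary and repair single frameshifts", {
  rec <- data.frame(read_id = sprintf("r%d", 1:6), ref_id = "ref",
                    identity = 0.99,
                    n_stop_codons = c(0, 0, 0, 1, 0, 0),
                    n_frameshifts = c(0, 0, 0, 1, 2, 1),
                    n_inserted_codons = c(0, 0, 0, 0, 0, 1),
                    n_deleted_codons = c(3, 4, 0, 0, 0, 0),
                    alignable = TRUE, sequence = "ACG",
                    repaired_seq = NA_character_)
  v <- apply_keep_rules(rec)$verdict
  expect_equal(v, c("pass",               # del = 3: fewer than four
                    "discard_deletion",   # del = 4: boundary
                    "pass",
                    "discard_stop",       # stop outranks frameshift
                    "discard_frameshift",
                    "discard_frameshift"))# fs=1 but insertion present
  # a real single-frameshift read is repaired to an in-frame stop-free insert
  panel <- small_panel()
  ref <- panel$qc_references[[5]]
  fsread <- paste0(substr(ref, 1, 100), substr(ref, 102, nchar(ref)))
  out <- apply_keep_rules(frame_classify(c(fs = fsread),
                                         panel$qc_references))
  expect_equal(out$verdict, "repaired")
  expect_equal(nchar(out$output_sequence) %% 3, 0)
  expect_length(translate_dna(out$output_sequence)$stops, 0)
  # the repair removes exactly the affected codon from the codon-complete span
  expect_equal(nchar(out$output_sequence),
               (nchar(ref) %/% 3 - 1) * 3)
})

test_that("chimera screen separates mosaics from clonal reads", {
  set.seed(24)
  r1 <- rand_dna(300)
  r2 <- mutate_seq(r1, 40)           # ~13% divergent parent
  refs <- c(p1 = r1, p2 = r2)
  chim <- paste0(substr(r1, 1, 150), substr(r2, 151, 300))
  res <- detect_chimera(c(chim = chim, clone1 = r1, clone2 = r2), refs)
  expect_equal(res$is_chimera, c(TRUE, FALSE, FALSE))
  expect_equal(res$score_gain[2:3], c(0, 0))
  expect_gt(res$best_two_parent_identity[1], res$best_single_identity[1])
  # breakpoint recovered near the construction point
  expect_lt(abs(res$breakpoint[1] - 150), 10)
  # identical references can never produce a gain
  same <- detect_chimera(c(x = r1), c(a = r1, b = r1))
  expect_false(same$is_chimera)
  expect_equal(same$score_gain, 0)
  # too-short reads are not evaluable
  short <- detect_chimera(c(s = substr(r1, 1, 50)), refs,
                          min_segment = 30)
  expect_false(short$evaluable)
  expect_false(short$is_chimera)
})

test_that("the pipeline recovers planted verdicts on a noise-free batch", {
  spec <- small_spec(verdict_mix = c(stop = 0.12, frameshift = 0.12,
                                     deletion4 = 0.06, insertion = 0.04,
                                     codon_deletion = 0.04,
                                     multi_frameshift = 0.04),
                     chimera_fraction = 0.02)
  panel <- small_panel()
  sim <- make_gut_reads(spec, panel)
  reps <- panel$qc_references[!duplicated(panel$species)]
  qc <- run_read_qc(sim$reads, sim$scheme, coi_primer("mlCOIintF"),
                    coi_primer("jgHCO2198"), panel$qc_references,
                    chimera_references = reps)
  truth <- sim$truth$expected_verdict[match(qc$records$read_id,
                                            sim$truth$read_id)]
  expect_gte(mean(qc$records$verdict == truth), 0.99)
  # demultiplexing partitions the input
  expect_equal(qc$summary$input, length(sim$reads))
  expect_equal(sum(unlist(qc$summary[c("pass", "repaired",
    "discard_chimera", "discard_stop", "discard_frameshift",
    "discard_insertion", "discard_deletion", "discard_primer",
    "discard_length", "unassigned")])), length(sim$reads))
  # repaired outputs are always in-frame and stop-free
  rep_seq <- qc$records$output_sequence[qc$records$verdict == "repaired"]
  expect_true(all(nchar(rep_seq) %% 3 == 0))
  for (s in rep_seq) expect_length(translate_dna(s)$stops, 0)
})
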