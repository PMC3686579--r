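# Seeded generators for every input class the pipeline consumes:
# codon-structured reference panels with lineages, entropy-profiled
# alignments with planted conserved windows, and tagged gut-content reads
# with exhaustive truth labels.
#
# The geometry mirrors the mini-barcode design: barcodes carry a 658 bp
# Folmer-style region (generated as 220 codons = 660 nt, frame 0 from
# position 1); the amplified insert is positions 346-658 (313 nt,
# beginning on a codon boundary), and the frame-QC references are the
# codon-complete 315 nt window 346-660.

.INSERT_START <- 346L
.INSERT_END <- 658L
.QC_REF_END <- 660L

.SIM_PHYLA <- c("Arthropoda", "Mollusca", "Annelida", "Chordata",
                "Cnidaria", "Echinodermata")

#' Specification for the synthetic-data generators
#'
#' Defaults describe the planted-violation study conditions used
#' throughout the test suite: 12 species diverged ~12% between and <=2%
#' within species, 16 one-gut samples tagged hierarchically (MID + 6-bp
#' tag), ~30% predator contamination, a planted verdict mix of 10%
#' stop-codon mutants, 10% single-frameshift reads and 5% four-codon
#' deletions, 1% two-parent chimeras, and no sequencing noise (noise is
#' opt-in via the error-model rates).
#'
#' @param seed Integer seed; the same seed gives byte-identical outputs.
#' @param n_species Number of species in the reference panel.
#' @param n_refs_per_species References (individuals) per species.
#' @param barcode_codons Barcode length in codons (default 220 = 660 nt).
#' @param intra_divergence,inter_divergence Target pairwise divergence
#'   within and between species (fractions; intra < inter).
#' @param n_samples Number of gut samples.
#' @param reads_per_sample Reads per sample.
#' @param predator_fraction Fraction of each sample's reads drawn from
#'   its predator's own barcode.
#' @param verdict_mix Named probabilities over planted read categories:
#'   `clean`, `stop`, `frameshift`, `codon_deletion` (1-3 codons, still
#'   functional), `deletion4`, `insertion`, `multi_frameshift`. Missing
#'   names default to 0; the remainder goes to `clean`.
#' @param chimera_fraction Fraction of reads built as two-parent chimeras
#'   (drawn before the verdict mix).
#' @param substitution_rate,homopolymer_indel_rate Per-base error-model
#'   rates (default 0).
#' @return A `sim_spec` object (validated list).
#' @export
sim_spec <- function(seed = 1L, n_species = 12L, n_refs_per_species = 3L,
                     barcode_codons = 220L, intra_divergence = 0.02,
                     inter_divergence = 0.12, n_samples = 16L,
                     reads_per_sample = 315L, predator_fraction = 0.3,
                     verdict_mix = c(stop = 0.10, frameshift = 0.10,
                                     deletion4 = 0.05),
                     chimera_fraction = 0.01,
                     substitution_rate = 0,
                     homopolymer_indel_rate = 0) {
  cats <- c("clean", "stop", "frameshift", "codon_deletion", "deletion4",
            "insertion", "multi_frameshift")
  mix <- stats::setNames(rep(0, length(cats)), cats)
  if (length(verdict_mix)) {
    bad <- setdiff(names(verdict_mix), cats)
    if (length(bad)) stop("unknown verdict_mix categories: ",
                          paste(bad, collapse = ", "))
    mix[names(verdict_mix)] <- verdict_mix
  }
  if (sum(mix[-1L]) > 1) stop("verdict_mix probabilities exceed 1")
  mix["clean"] <- 1 - sum(mix[-1L])
  rates <- c(intra_divergence, inter_divergence, predator_fraction,
             chimera_fraction, substitution_rate, homopolymer_indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (intra_divergence >= inter_divergence)
    stop("intra-species divergence must be below inter-species divergence")
  L <- 3L * barcode_codons
  if (L < .QC_REF_END)
    stop("barcode_codons must be at least ", ceiling(.QC_REF_END / 3))
  n_mut <- round(inter_divergence / 2 * L)
  if (n_species * n_mut > L)
    stop("infeasible spec: requested inter-species divergence needs more ",
         "disjoint sites than the barcode has")
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    n_refs_per_species = as.integer(n_refs_per_species),
    barcode_codons = as.integer(barcode_codons),
    intra_divergence = intra_divergence,
    inter_divergence = inter_divergence,
    n_samples = as.integer(n_samples),
    reads_per_sample = as.integer(reads_per_sample),
    predator_fraction = predator_fraction, verdict_mix = mix,
    chimera_fraction = chimera_fraction,
    substitution_rate = substitution_rate,
    homopolymer_indel_rate = homopolymer_indel_rate), class = "sim_spec")
}

.BASES <- c("A", "C", "G", "T")

# all non-stop codons under the given code
.safe_codons <- function(code = "5") {
  all64 <- expand_primer("NNN")
  setdiff(all64, .stop_codons(code))
}

# mutate `chars` at `positions` to a different base without creating an
# in-frame stop (frame 0)
.mutate_safely <- function(chars, positions, stops) {
  for (p in positions) {
    c0 <- ((p - 1L) %/% 3L) * 3L + 1L
    for (b in sample(setdiff(.BASES, chars[p]))) {
      cand <- chars
      cand[p] <- b
      if (!(paste(cand[c0:(c0 + 2L)], collapse = "") %in% stops)) {
        chars <- cand
        break
      }
    }
  }
  chars
}

#' Generate a codon-structured reference panel
#'
#' Builds `n_species` stop-free frame-0 barcodes diverged by mutating
#' disjoint per-species site strata (so pairwise inter-species divergence
#' is the sum of the two species' strata), plus `n_refs_per_species`
#' intra-species variants each, a consistent synthetic lineage table, and
#' the codon-complete frame-QC reference window.
#'
#' @param spec A [sim_spec()].
#' @param code NCBI genetic code id (default "5").
#' @return List with `sequences` (named vector of full barcodes),
#'   `qc_references` (the 315 nt in-frame window per reference),
#'   `inserts` (the 313 nt amplified insert per reference), `lineage`
#'   (data frame), `species` (per-reference species), and `spec`.
#' @export
make_reference_panel <- function(spec, code = "5") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  stops <- .stop_codons(code)
  L <- 3L * spec$barcode_codons
  ancestor <- unlist(strsplit(sample(.safe_codons(code),
                                     spec$barcode_codons, replace = TRUE),
                              "", fixed = TRUE))
  n_mut <- round(spec$inter_divergence / 2 * L)
  strata <- split(sample.int(L)[seq_len(spec$n_species * n_mut)],
                  rep(seq_len(spec$n_species), each = n_mut))
  n_intra <- round(spec$intra_divergence / 2 * L)

  seqs <- character(0)
  species <- character(0)
  rows <- list()
  for (s in seq_len(spec$n_species)) {
    base <- .mutate_safely(ancestor, strata[[s]], stops)
    sp_name <- sprintf("Species_%02d", s)
    for (r in seq_len(spec$n_refs_per_species)) {
      v <- if (n_intra > 0L)
        .mutate_safely(base, sample.int(L, n_intra), stops) else base
      id <- sprintf("sp%02d_ref%d", s, r)
      seqs[id] <- paste(v, collapse = "")
      species[id] <- sp_name
      rows[[id]] <- data.frame(
        seq_id = id, kingdom = "Animalia",
        phylum = .SIM_PHYLA[(ceiling(s / 6) - 1L) %% length(.SIM_PHYLA) + 1L],
        class = sprintf("Class_%02d", ceiling(s / 8)),
        order = sprintf("Order_%02d", ceiling(s / 6)),
        family = sprintf("Family_%02d", ceiling(s / 4)),
        genus = sprintf("Genus_%02d", ceiling(s / 2)),
        species = sp_name)
    }
  }
  lineage <- do.call(rbind, rows)
  rownames(lineage) <- NULL
  list(sequences = seqs,
       qc_references = substr(seqs, .INSERT_START, .QC_REF_END),
       inserts = substr(seqs, .INSERT_START, .INSERT_END),
       lineage = lineage, species = species, spec = spec)
}

#' Measured divergence of a reference panel
#'
#' Mean pairwise Hamming divergence within and between species; used to
#' verify that generated panels satisfy their own specification.
#'
#' @param panel Output of [make_reference_panel()].
#' @return List with `intra` and `inter` (fractions; `intra` is `NA` with
#'   a single reference per species).
#' @export
panel_divergence <- function(panel) {
  mat <- do.call(rbind, strsplit(unname(panel$sequences), "", fixed = TRUE))
  sp <- unname(panel$species)
  n <- nrow(mat)
  intra <- inter <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- mean(mat[i, ] != mat[j, ])
    if (sp[i] == sp[j]) intra <- c(intra, d) else inter <- c(inter, d)
  }
  list(intra = if (length(intra)) mean(intra) else NA_real_,
       inter = mean(inter))
}

#' Generate an alignment with a planted conserved window
#'
#' Rows are unrelated (uniform-random) at every column except the planted
#' window. With `window_mode = "balanced"`, window columns realize the
#' base set of the corresponding IUPAC symbol at exactly equal
#' frequencies (so a degenerate consensus recovers the symbol); with
#' `"constant"` they are invariant (entropy exactly 0). Non-window
#' columns are guaranteed non-constant.
#'
#' @param n_rows Number of sequences.
#' @param n_cols Alignment width.
#' @param window_start 1-based start column of the window.
#' @param window_iupac IUPAC string planted in the window.
#' @param window_mode `"balanced"` or `"constant"`.
#' @param seed Integer seed.
#' @return Character vector of aligned rows.
#' @export
make_entropy_alignment <- function(n_rows = 500L, n_cols = 658L,
                                   window_start = 320L,
                                   window_iupac = "GGWACWGGWTGAACWGTWTAYCCYCC",
                                   window_mode = c("balanced", "constant"),
                                   seed = 1L) {
  window_mode <- match.arg(window_mode)
  stopifnot(n_rows >= 2L)
  syms <- .iupac_chars(window_iupac)
  stopifnot(window_start + length(syms) - 1L <= n_cols)
  set.seed(seed)
  mat <- matrix(sample(.BASES, n_rows * n_cols, replace = TRUE),
                nrow = n_rows)
  # non-window columns must not be accidentally constant
  for (j in seq_len(n_cols)) {
    while (length(unique(mat[, j])) == 1L)
      mat[1L, j] <- sample(.BASES, 1L)
  }
  for (k in seq_along(syms)) {
    j <- window_start + k - 1L
    set <- .IUPAC_SETS[[syms[k]]]
    mat[, j] <- if (window_mode == "constant") set[1L]
      else sample(rep_len(set, n_rows))  # exact equal frequencies
  }
  apply(mat, 1L, paste, collapse = "")
}

# default hierarchical tag scheme: tags T1-T5 crossed with library MIDs
.default_scheme <- function(n_samples) {
  tags <- coi_sample_tags()
  mids <- c(MID1 = "ACGAGTGCGT", MID2 = "ACGCTCGACA", MID3 = "AGACGCACTC",
            MID4 = "AGCACTGTAG")
  combos <- expand.grid(tag = seq_len(nrow(tags)), mid = seq_along(mids))
  if (n_samples > nrow(combos))
    stop("scheme supports at most ", nrow(combos), " samples")
  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             mid = unname(mids[combos$mid[seq_len(n_samples)]]),
             tag = tags$tag[combos$tag[seq_len(n_samples)]])
}

.hpol_indel <- function(chars) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  runs <- which(r$lengths >= 2L & ends > 20L & ends < length(chars) - 20L)
  if (length(runs)) {
    k <- if (length(runs) == 1L) runs else sample(runs, 1L)
    p <- ends[k]
    if (stats::runif(1) < 0.5) chars[-p]               # drop one base
    else append(chars, chars[p], after = p)            # duplicate one base
  } else {
    p <- sample(seq(20L, length(chars) - 20L), 1L)
    append(chars, sample(.BASES, 1L), after = p)
  }
}

#' Generate tagged gut-content reads with truth labels
#'
#' Per sample, reads are drawn from a prey mixture plus the predator's
#' own barcode at the contamination fraction; planted anomalies
#' (stop-codon mutants, homopolymer-adjacent single-base indels,
#' whole-codon insertions/deletions, two-parent chimeras) follow the
#' spec's verdict mix and every read is labelled in the truth table.
#' Reads carry the full layout MID + tag + forward-primer member +
#' insert + revcomp(reverse-primer member) + revcomp(tag), using concrete
#' expansion members of the mlCOIintF/jgHCO2198 pair.
#'
#' @param spec A [sim_spec()].
#' @param panel Output of [make_reference_panel()] for the same spec.
#' @return List with `reads` (named character), `truth` (data frame:
#'   read_id, sample_id, source species/reference, planted category,
#'   expected verdict, chimera annotation), `scheme` (sample_id, mid,
#'   tag, predator_species) and `spec`.
#' @export
make_gut_reads <- function(spec, panel) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)
  scheme <- .default_scheme(spec$n_samples)
  pred_sp <- sprintf("Species_%02d",
                     (seq_len(spec$n_samples) - 1L) %% 3L + 1L)
  scheme$predator_species <- pred_sp
  fwd_members <- expand_primer(coi_primer("mlCOIintF"))
  rev_members <- expand_primer(coi_primer("jgHCO2198"))
  inserts <- panel$inserts
  ref_sp <- panel$species
  stops <- .stop_codons("5")
  exp_verdict <- c(clean = "pass", stop = "discard_stop",
                   frameshift = "repaired", codon_deletion = "pass",
                   deletion4 = "discard_deletion",
                   insertion = "discard_insertion",
                   multi_frameshift = "discard_frameshift")

  reads <- character(0)
  truth <- list()
  for (s in seq_len(spec$n_samples)) {
    sid <- scheme$sample_id[s]
    n <- spec$reads_per_sample
    n_pred <- round(spec$predator_fraction * n)
    pred_refs <- names(ref_sp)[ref_sp == pred_sp[s]]
    prey_refs <- names(ref_sp)[ref_sp != pred_sp[s]]
    src <- c(sample(pred_refs, n_pred, replace = TRUE),
             sample(prey_refs, n - n_pred, replace = TRUE))
    src <- sample(src)  # shuffle predator/prey order
    is_chim <- stats::runif(n) < spec$chimera_fraction
    category <- ifelse(is_chim, "chimera",
                       sample(names(spec$verdict_mix), n, replace = TRUE,
                              prob = spec$verdict_mix))
    for (i in seq_len(n)) {
      ins <- inserts[[src[i]]]
      cat_i <- category[i]
      parent2 <- NA_character_
      if (cat_i == "chimera") {
        parent2 <- sample(names(ref_sp)[ref_sp != ref_sp[src[i]]], 1L)
        # breakpoints in the central third: both parent segments must be
        # long enough to carry a diagnosable divergence signal
        b <- sample(seq(ceiling(nchar(ins) / 3),
                        floor(2 * nchar(ins) / 3)), 1L)
        ins <- paste0(substr(ins, 1L, b),
                      substr(inserts[[parent2]], b + 1L, nchar(ins)))
      } else if (cat_i == "stop") {
        cd <- sample(5:100, 1L)
        substr(ins, 3L * cd - 2L, 3L * cd) <- "TAA"
      } else if (cat_i == "frameshift") {
        ins <- paste(.hpol_indel(strsplit(ins, "", fixed = TRUE)[[1L]]),
                     collapse = "")
      } else if (cat_i == "codon_deletion") {
        k <- sample(1:3, 1L)
        cd <- sample(5:(100 - k), 1L)
        ins <- paste0(substr(ins, 1L, 3L * (cd - 1L)),
                      substr(ins, 3L * (cd + k - 1L) + 1L, nchar(ins)))
      } else if (cat_i == "deletion4") {
        cd <- sample(5:96, 1L)
        ins <- paste0(substr(ins, 1L, 3L * (cd - 1L)),
                      substr(ins, 3L * (cd + 3L) + 1L, nchar(ins)))
      } else if (cat_i == "insertion") {
        cd <- sample(5:100, 1L)
        ins <- paste0(substr(ins, 1L, 3L * cd),
                      sample(.safe_codons("5"), 1L),
                      substr(ins, 3L * cd + 1L, nchar(ins)))
      } else if (cat_i == "multi_frameshift") {
        ch <- strsplit(ins, "", fixed = TRUE)[[1L]]
        p <- sort(sample(seq(20L, length(ch) - 20L), 2L))
        if (p[2L] - p[1L] < 10L) p[2L] <- p[1L] + 10L
        ch <- append(ch, sample(.BASES, 1L), after = p[2L])
        ch <- ch[-p[1L]]
        ins <- paste(ch, collapse = "")
      }
      if (spec$substitution_rate > 0) {
        ch <- strsplit(ins, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(ch)) < spec$substitution_rate)
        if (length(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(.BASES, b), 1L), "")
        ins <- paste(ch, collapse = "")
      }
      if (spec$homopolymer_indel_rate > 0 &&
          stats::runif(1) < spec$homopolymer_indel_rate * nchar(ins)) {
        ins <- paste(.hpol_indel(strsplit(ins, "", fixed = TRUE)[[1L]]),
                     collapse = "")
      }
      rid <- sprintf("%s_r%04d", sid, i)
      reads[rid] <- paste0(
        scheme$mid[s], scheme$tag[s], sample(fwd_members, 1L), ins,
        reverse_complement(sample(rev_members, 1L)),
        reverse_complement(scheme$tag[s]))
      truth[[rid]] <- data.frame(
        read_id = rid, sample_id = sid, source_ref = src[i],
        source_species = unname(ref_sp[src[i]]), category = cat_i,
        expected_verdict = if (cat_i == "chimera") "discard_chimera"
                           else unname(exp_verdict[cat_i]),
        chimera_parent2 = parent2)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(reads = reads, truth = truth, scheme = scheme, spec = spec)
}

#' Write a simulated read set to disk
#'
#' Emits `reads.fastq` (constant high quality), `truth.tsv` and
#' `scheme.tsv` into `dir`.
#'
#' @param sim Output of [make_gut_reads()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_reads <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$reads)
  qual <- Biostrings::BStringSet(vapply(nchar(sim$reads), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(dna, file.path(dir, "reads.fastq"),
                              format = "fastq", qualities = qual)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$scheme, file.path(dir, "scheme.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a reference panel to disk
#'
#' Emits `references.fasta`, `qc_references.fasta` and `lineage.tsv`.
#'
#' @param panel Output of [make_reference_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$sequences),
                              file.path(dir, "references.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(panel$qc_references),
    file.path(dir, "qc_references.fasta"))
  write.table(panel$lineage, file.path(dir, "lineage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
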