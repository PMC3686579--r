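# Entropy profiling, conserved-window discovery, degenerate consensus,
# blocking-primer design.

test_that("column entropy has the documented fixed points and bounds", {
  expect_equal(column_entropy(c(A = 100)), 0)
  expect_equal(column_entropy(c(A = 25, C = 25, G = 25, T = 25)), 2)
  expect_equal(column_entropy(c(A = 50, T = 50)), 1)
  expect_error(column_entropy(c(A = 0, C = 0)), "undefined")
  set.seed(4)
  for (i in 1:20) {
    h <- column_entropy(runif(4, 0, 10))
    expect_gte(h, 0)
    expect_lte(h, 2)
  }
})

test_that("alignment profiling counts ambiguity fractionally and flags gaps", {
  # two identical rows: entropy 0 everywhere
  pr <- profile_alignment(c("ACGTACGT", "ACGTACGT"))
  expect_equal(pr$entropy, rep(0, 8))
  # R splits 1/2 A + 1/2 G: column {A,A,R,R} -> A:3, G:1
  pr <- profile_alignment(c("A", "A", "R", "R"))
  expect_equal(unname(pr$counts[, 1]), c(3, 0, 1, 0))
  # drop mode discards ambiguous residues entirely
  pr_drop <- profile_alignment(c("A", "A", "R", "R"), ambiguous = "drop")
  expect_equal(unname(pr_drop$counts[, 1]), c(2, 0, 0, 0))
  # gaps: excluded from entropy, tracked as coverage; all-gap is NA
  pr <- profile_alignment(c("A-", "A-"))
  expect_equal(pr$coverage, c(1, 0))
  expect_true(is.na(pr$entropy[2]))
  expect_equal(pr$entropy[1], 0)
  # ragged alignment rejected naming rows
  expect_error(profile_alignment(c("ACGT", "ACG")), "row")
})

test_that("entropy is zero iff one base has frequency one", {
  aln <- make_entropy_alignment(n_rows = 50, n_cols = 120, window_start = 40,
                                window_iupac = "AAAAAAAAAA",
                                window_mode = "constant", seed = 9)
  pr <- profile_alignment(aln)
  expect_equal(which(pr$entropy == 0), 40:49)
})

test_that("conserved windows are found at the planted locus, invariant to row order", {
  aln <- make_entropy_alignment(n_rows = 120, seed = 5)  # window at 320-345
  pr <- profile_alignment(aln)
  w <- find_conserved_windows(pr, width = 26, max_mean_entropy = 1.2)
  expect_equal(c(w$start[1], w$end[1]), c(320, 345))
  # row order must not matter
  pr2 <- profile_alignment(rev(aln))
  w2 <- find_conserved_windows(pr2, width = 26, max_mean_entropy = 1.2)
  expect_equal(w, w2)
  # all-constant alignment: every window qualifies with mean entropy 0
  prc <- profile_alignment(rep(strrep("ACGT", 10), 5))
  wc <- find_conserved_windows(prc, width = 10, max_mean_entropy = 0)
  expect_equal(nrow(wc), 31)
  expect_true(all(wc$mean_entropy == 0))
  # width beyond the alignment is a precondition error
  expect_error(find_conserved_windows(prc, width = 100), "width")
  # nothing qualifying: empty result, not an error
  expect_equal(nrow(find_conserved_windows(pr, 26, max_mean_entropy = -1)), 0)
})

test_that("degenerate consensus covers bases above the frequency floor", {
  # 97% A / 3% G at floor 0.05 -> plain A
  aln <- c(rep("A", 97), rep("G", 3))
  pr <- profile_alignment(aln)
  expect_equal(degenerate_consensus(pr, 1, 1, 0.05)$sequence, "A")
  # 50/50 A/T -> W
  pr <- profile_alignment(c("A", "T"))
  expect_equal(degenerate_consensus(pr, 1, 1, 0.05)$sequence, "W")
  # planted-window fixture round-trips the mini-barcode forward primer
  aln <- make_entropy_alignment(n_rows = 200, seed = 5)
  pr <- profile_alignment(aln)
  expect_equal(degenerate_consensus(pr, 320, 345)$sequence,
               "GGWACWGGWTGAACWGTWTAYCCYCC")
})

test_that("consensus at floor 0 round-trips a primer from its expansion", {
  set.seed(6)
  for (i in 1:10) {
    p <- rand_primer(sample(4:8, 1))
    if (degeneracy(p) > 512) next
    pr <- profile_alignment(expand_primer(p))
    expect_equal(degenerate_consensus(pr, 1, nchar(p), 0)$sequence, p)
  }
})

test_that("blocking primers extend into predator-specific sequence", {
  set.seed(7)
  predator <- rand_dna(120)
  # universal forward site at 21-45; extension 46-60
  site <- list(strand = "+", start = 21L, end = 45L)
  prey <- vapply(1:5, function(i) {
    # prey share the priming site but differ at >= 4 extension positions
    p <- predator
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    pos <- sample(46:60, 5)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), "")
    paste(ch, collapse = "")
  }, "")
  bp <- design_blocking_primer(predator, site, overlap_len = 10,
                               total_len = 25, prey_refs = prey,
                               min_prey_mismatches = 4)
  expect_s3_class(bp, "blocking_primer")
  expect_true(bp$three_prime_block)
  expect_equal(nchar(bp$sequence), 25)
  expect_gte(min(bp$prey_mismatches), 4)
  expect_equal(bp$overlap_span, c(36, 45))
  expect_equal(bp$extension_span, c(46, 60))
  expect_equal(bp$sequence, substr(predator, 36, 60))
  # the predator itself as "prey" has zero extension mismatches: rejected
  expect_error(design_blocking_primer(predator, site, 10, 25,
                                      c(prey, self = predator)),
               "self")
  # reverse-strand universal site: blocker is the reverse complement
  rsite <- list(strand = "-", start = 61L, end = 85L)
  bp2 <- design_blocking_primer(predator, rsite, overlap_len = 10,
                                total_len = 25, prey_refs = prey,
                                min_prey_mismatches = 0)
  expect_equal(bp2$sequence, reverse_complement(substr(predator, 46, 70)))
})
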