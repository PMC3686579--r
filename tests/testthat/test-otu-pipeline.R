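# OTU clustering, taxonomy, tables, diet summaries, rarefaction.

test_that("greedy clustering has the documented degenerate behaviors", {
  reads <- setNames(rep("ACGTACGTACGTACGTACGTACGTACGTACGT", 20),
                    sprintf("r%d", 1:20))
  ot <- cluster_otus(reads, radius = 0.07)
  expect_equal(nrow(ot$otus), 1)
  expect_equal(ot$otus$n_reads, 20)
  # radius 0: one OTU per unique sequence
  set.seed(30)
  uniq <- replicate(5, rand_dna(60))
  ot0 <- cluster_otus(setNames(c(uniq, uniq), sprintf("r%d", 1:10)),
                      radius = 0)
  expect_equal(nrow(ot0$otus), 5)
  expect_true(all(ot0$otus$n_reads == 2))
})

test_that("clustering recovers planted centroids and matches brute force", {
  set.seed(31)
  c1 <- rand_dna(200)
  c2 <- mutate_seq(c1, 30)  # 15% divergent
  sats <- c(c1 = c1, c2 = c2,
            s11 = mutate_seq(c1, 3), s12 = mutate_seq(c1, 4),
            s21 = mutate_seq(c2, 2), s22 = mutate_seq(c2, 4))
  # abundances: centroids most abundant
  reads <- rep(sats, times = c(10, 9, 2, 2, 2, 1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  ot <- cluster_otus(reads, radius = 0.07)
  expect_equal(nrow(ot$otus), 2)
  expect_setequal(ot$otus$representative, c(c1, c2))
  # brute force: pairwise Hamming distances + the same greedy rule
  uniq <- unique(reads)
  ab <- table(factor(reads, levels = uniq))
  ord <- order(-as.integer(ab), uniq)
  uniq <- uniq[ord]
  cents <- character(0); assign <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    d <- vapply(cents, function(cc) hamming(uniq[i], cc) / 200, 0)
    w <- which(d <= 0.07)
    if (length(w)) assign[i] <- w[1]
    else { cents <- c(cents, uniq[i]); assign[i] <- length(cents) }
  }
  oracle <- lapply(seq_along(cents), function(o)
    sort(names(reads)[reads %in% uniq[assign == o]]))
  got <- lapply(ot$members, sort)
  expect_setequal(unname(got), oracle)
  # invariants: partition, conservation, members within the radius
  expect_setequal(unlist(ot$members), names(reads))
  expect_equal(sum(ot$otus$n_reads), length(reads))
  for (o in seq_len(nrow(ot$otus))) {
    rep_seq <- ot$otus$representative[o]
    for (m in unique(reads[ot$members[[o]]]))
      expect_lte(1 - pairwise_identity(m, rep_seq), 0.07)
  }
})

make_ref_db <- function() {
  set.seed(32)
  base <- rand_dna(300)
  refs <- c(refA = base,
            refB = mutate_seq(base, 12),   # same genus as A
            refC = mutate_seq(base, 40))   # same family, other genus
  lineage <- data.frame(
    seq_id = names(refs), kingdom = "Animalia", phylum = "Arthropoda",
    class = "Malacostraca", order = "Decapoda", family = "Alpheidae",
    genus = c("Alpheus", "Alpheus", "Synalpheus"),
    species = c("Alpheus alpha", "Alpheus beta", "Synalpheus gamma"))
  list(refs = refs, lineage = lineage, base = base)
}

test_that("species assignment is inclusive at the 98% threshold", {
  db <- make_ref_db()
  q99 <- mutate_seq(db$base, 3, seed = 33)    # 99% identity
  q98 <- mutate_seq(db$base, 6, seed = 34)    # exactly 98.0%
  q97 <- mutate_seq(db$base, 9, seed = 35)    # 97%: below threshold
  asn <- assign_taxonomy(c(a = q99, b = q98, c = q97), db$refs, db$lineage)
  expect_equal(asn$method, c("species_match", "species_match",
                             "rank_consensus"))
  expect_equal(asn$best_identity[2], 0.98)
  expect_equal(asn$species[1:2], rep("Alpheus alpha", 2))
  # 97% falls in the genus band; hits >= 95% are refA only -> genus
  expect_equal(asn$assigned_rank[3], "genus")
  expect_equal(asn$genus[3], "Alpheus")
  expect_true(is.na(asn$species[3]))
})

test_that("rank consensus coarsens with identity and divergent hits", {
  db <- make_ref_db()
  # ~90%: band floor 0.90 spans refA and refB (two Alpheus species) and
  # refC is below the floor -> genus-level consensus within the band
  q90 <- mutate_seq(db$base, 30, seed = 36)
  asn <- assign_taxonomy(c(q = q90), db$refs, db$lineage)
  expect_equal(asn$method, "rank_consensus")
  expect_true(asn$assigned_rank %in% c("family", "genus"))
  # far below every band: unidentified with empty path
  junk <- paste(rep("ACGT", 75), collapse = "")
  asn2 <- assign_taxonomy(c(q = junk), db$refs, db$lineage)
  expect_equal(asn2$method, "unidentified")
  expect_true(all(is.na(asn2[c("phylum", "genus", "species")])))
})

test_that("assignment rank is monotone in identity", {
  db <- make_ref_db()
  rank_order <- c(unidentified = 0, kingdom = 1, phylum = 2, class = 3,
                  order = 4, family = 5, genus = 6, species = 7)
  set.seed(37)
  ranks <- sapply(c(60, 45, 30, 20, 12, 6, 2, 0), function(k) {
    a <- assign_taxonomy(c(q = mutate_seq(db$base, k)), db$refs,
                         db$lineage)
    r <- a$assigned_rank
    if (is.na(r)) "unidentified" else r
  })
  expect_true(all(diff(rank_order[ranks]) >= 0))
})

test_that("the OTU table conserves counts and bins abundance classes", {
  set.seed(38)
  seqs <- c(rand_dna(120), rand_dna(120), rand_dna(120))
  reads <- setNames(rep(seqs, c(1, 5, 12)), sprintf("r%02d", 1:18))
  smap <- setNames(rep(c("g1", "g2", "g1"), c(6, 10, 2)), names(reads))
  ot <- cluster_otus(reads, radius = 0.07)
  tab <- build_otu_table(ot, smap)
  expect_equal(sum(tab$table), 18)
  expect_equal(sort(unname(rowSums(tab$table))), c(1, 5, 12))
  expect_equal(unname(tab$abundance_classes[c("1", "2-9", "10-99")]),
               c(1L, 1L, 1L), ignore_attr = TRUE)
  # a sample with no retained reads keeps its zero column
  tab2 <- build_otu_table(ot, c(smap, unused_read = "g3"))
  expect_equal(ncol(tab2$table), 3)
  expect_equal(sum(tab2$table[, "g3"]), 0)
  # a member without a sample is a hard upstream error
  expect_error(build_otu_table(ot, smap[-1]), "without sample_id")
})

test_that("predator-self OTUs are removed, congeners retained", {
  tab <- matrix(c(5, 0, 3, 2, 0, 7), nrow = 3,
                dimnames = list(c("OTU_1", "OTU_2", "OTU_3"),
                                c("s1", "s2")))
  asn <- data.frame(
    query_id = c("OTU_1", "OTU_2", "OTU_3"),
    method = c("species_match", "species_match", "unidentified"),
    species = c("Myripristis berndti", "Myripristis murdjan", NA))
  preds <- c(s1 = "Myripristis berndti", s2 = "Sargocentron microstoma")
  rs <- remove_self_otus(tab, asn, preds)
  expect_equal(rs$removed$otu_id, "OTU_1")       # the predator itself
  expect_setequal(rownames(rs$table), c("OTU_2", "OTU_3"))  # congener kept
})

test_that("diet summaries match hand enumeration", {
  # two species, 2 + 2 individuals; occurrence structure by construction
  tab <- matrix(c(
    # a1 a2 b1 b2
    1, 1, 0, 0,   # OTU_1: both A individuals        -> A: in 2
    1, 0, 0, 0,   # OTU_2: one A individual          -> A: in 1
    1, 1, 1, 0,   # OTU_3: both A + one B            -> shared
    0, 0, 1, 1,   # OTU_4: both B                    -> B: in 2
    0, 0, 0, 1),  # OTU_5: one B                     -> B: in 1
    nrow = 5, byrow = TRUE,
    dimnames = list(sprintf("OTU_%d", 1:5), c("a1", "a2", "b1", "b2")))
  preds <- c(a1 = "SpA", a2 = "SpA", b1 = "SpB", b2 = "SpB")
  ds <- diet_summaries(tab, preds)
  intra <- ds$intraspecific
  expect_equal(intra$n_otus, c(3, 3))
  expect_equal(intra$n_in_1, c(1, 2))
  expect_equal(intra$n_in_2, c(2, 1))
  expect_equal(intra$n_in_gt2, c(0, 0))
  inter <- ds$interspecific
  expect_equal(inter$n_shared, c(1, 1))          # OTU_3 in both species
  expect_equal(inter$prop_shared, c(1 / 3, 1 / 3))
  # single individual: all its OTUs occur in exactly one individual
  ds1 <- diet_summaries(tab[, "a1", drop = FALSE], preds["a1"])
  expect_equal(ds1$intraspecific$prop_in_1, 1)
  # disjoint species: zero interspecific sharing
  tab2 <- tab; tab2["OTU_3", c("b1")] <- 0
  ds2 <- diet_summaries(tab2, preds)
  expect_equal(ds2$interspecific$n_shared, c(0, 0))
})

test_that("analytic rarefaction matches exhaustive and Monte-Carlo subsampling", {
  # exhaustive oracle on (5, 3, 2) at depth 4: all C(10, 4) subsamples
  pool <- rep(1:3, c(5, 3, 2))
  subs <- combn(10, 4)
  oracle <- mean(apply(subs, 2, function(ix) length(unique(pool[ix]))))
  rc <- rarefaction_curve(c(5, 3, 2), 4)
  expect_equal(rc$expected_otus, oracle)
  # fixed points
  expect_equal(rarefaction_curve(c(5, 3, 2), 1)$expected_otus, 1)
  expect_equal(rarefaction_curve(c(5, 3, 2), 10)$expected_otus, 3)
  expect_error(rarefaction_curve(c(5, 3, 2), 11), "exceeds")
  # monotone non-decreasing
  curve <- rarefaction_curve(c(40, 12, 5, 1, 1), 1:59)$expected_otus
  expect_true(all(diff(curve) >= 0))
  # agreement with the vegan implementation (independent cross-check)
  skip_if_not_installed("vegan")
  ab <- c(40, 12, 5, 1, 1)
  expect_equal(rarefaction_curve(ab, c(5, 20, 50))$expected_otus,
               as.numeric(vegan::rarefy(ab, c(5, 20, 50))),
               tolerance = 1e-10)
  # Monte-Carlo agreement within 3 standard errors
  set.seed(39)
  pool2 <- rep(seq_along(ab), ab)
  mc <- replicate(1000, length(unique(sample(pool2, 17))))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - rarefaction_curve(ab, 17)$expected_otus),
            3 * se)
})
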