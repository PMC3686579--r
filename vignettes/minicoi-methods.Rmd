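---
title: "minicoi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{minicoi: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`minicoi` implements the computational workflow around a COI
mini-barcode: designing a degenerate primer at a conserved site inside
the 658 bp Folmer barcode region, evaluating it by in-silico PCR, and
processing the tagged amplicon reads it produces into a
taxonomically annotated OTU table. This vignette records the models,
the parameters that matter, and the design choices that were genuinely
open, so that users know exactly what each number means — and what the
synthetic-data tests do and do not demonstrate about real data.

## Primer model

A degenerate primer is a string of IUPAC symbols, each denoting a base
set; a synthesis run produces every concrete combination, so the *fold
degeneracy* is the product of the per-position set sizes. Inosine is
handled asymmetrically, on purpose: it contributes a factor of **1** to
degeneracy (one physical base in the tube) but expands to all four
bases in `expand_primer()` (it anneals to anything, so all four
concrete sequences are realizable binding behavior). Both conventions
are needed: the first matches how degeneracy figures are quoted for
primer mixes, the second is what in-silico annealing requires.
`expand_primer()` refuses expansions beyond a cap (default 65,536) so a
stray `NNNNNNNN` cannot blow up memory.

The reverse complement is a per-symbol complement plus reversal
(R↔Y, K↔M; W, S, N, I self-complementary) and is an involution that
preserves degeneracy — both properties are asserted in the tests. Note
that the shipped `mlCOIintR` is stored exactly as printed; it is *not*
the literal reverse complement of `mlCOIintF` (five positions carry S
where the literal reverse complement has W). The package exposes
`reverse_complement()` so users can compare the two; it does not guess
which was intended. This has one practical consequence: no concrete
template window can match both primers at zero mismatches, so geometry
checks involving `mlCOIintR` anneal it at a five-mismatch tolerance
(exactly the S/W positions).

Translation defaults to the invertebrate mitochondrial code (NCBI
table 5), the appropriate code for a metazoan mitochondrial marker:
under it AGA/AGG are serine and TGA tryptophan, so screening
pseudogenes with the standard code would miscount stop codons. The
code is a parameter (`code = "5"`) everywhere it matters.

## Entropy profiling and consensus design

Columns of a barcode alignment are summarized by Shannon entropy in
bits, $h(x) = -\sum_b f_b \log_2 f_b$, computed over A/C/G/T
frequencies; 0 bits means invariant, 2 bits means all four bases
equally frequent. The unit (log base 2) is fixed and documented here
because entropy plots in the literature frequently leave it unlabeled.
Three handling rules, all parameters of `profile_alignment()` /
`find_conserved_windows()`:

- Ambiguity symbols contribute fractionally ($1/|{\rm set}|$ to each
  base they denote); `ambiguous = "drop"` discards them instead.
- Gaps never enter the frequencies; they are tracked as per-column
  *coverage*, and windows containing columns below `min_coverage`
  (default 0.9) are disqualified. An all-gap column has *undefined*
  entropy (`NA`), never 0 — conflating "no data" with "perfectly
  conserved" would be the worst possible failure mode for primer
  design.
- Windows are ranked by mean entropy ascending, ties by max entropy,
  then by start coordinate; the `max_mean_entropy` ceiling (default
  0.25 bits) is a toolkit parameter — "limited variation" has no
  canonical threshold, so the default is deliberately strict and meant
  to be relaxed per dataset.

`degenerate_consensus()` turns a window into a primer: per column, the
IUPAC symbol covering exactly the bases at frequency ≥ `min_base_freq`
(default 0.05; the modal base is always included). At
`min_base_freq = 0` over the expansion of a primer it returns that
primer — the round-trip property the tests assert. Coordinates in all
reports are 1-based inclusive.

Blocking primers follow the published design logic: overlap the 3' end
of a universal priming site by `overlap_len` bases, extend
`total_len − overlap_len` bases into adjacent predator-specific
sequence, and carry a 3' Spacer-C3 so they anneal without extending. A
candidate is rejected unless *every* prey reference shows at least
`min_prey_mismatches` (default 4) differences in the extension region —
the design constraint that keeps prey amplifiable.

## In-silico PCR

Annealing is gapless IUPAC set intersection: a position mismatches iff
the primer and template base sets are disjoint; inosine never
mismatches; template N is a wildcard by default (`strict_N` flips
that). No 3'-weighting is applied, matching how mismatch distributions
are conventionally reported as raw counts; thermodynamics (melting
temperature, secondary structure) are out of scope. Binding sites are
searched on both strands; amplicons are all properly oriented
forward/reverse site pairs, with the insert excluding both footprints.
`mismatch_distribution()` uses each reference's minimum-mismatch site
(leftmost on ties), or a fixed window when coordinates are supplied —
both modes exist because delimiting a "priming site" by search versus
by alignment coordinates are both defensible. References with no site
within a generous ceiling land in an explicit unalignable tally.

## Read QC

The pipeline assumes reads laid out as
`MID + tag + forward primer + insert + revcomp(reverse primer) + revcomp(tag)`.
Demultiplexing matches MID and 6-bp tag exactly (a configurable tag
tolerance exists but defaults to 0 — only the primer regions have a
published mismatch rule); each primer region tolerates
`max_primer_mismatches` (default 2, so a third mismatch discards the
read). The minimum trimmed-insert length (default 150 nt) is this
package's base-space counterpart of a pyrosequencing flow-count floor:
flow counts have no exact base-space equivalent, so the filter is
re-expressed as a length, and the default is stated rather than
inherited.

Frame classification aligns each read to its closest in-frame
reference — shared 8-mer prescreen, then affine-gap alignment with the
read global and the reference ends free (match +1, mismatch −2, gap
open 10, extension 1; logged here because they are toolkit choices,
not published values). The reading frame is inherited through the
alignment. Gap runs whose length is a multiple of 3 are whole-codon
insertions/deletions; any other run is a frameshift; stop codons are
counted on the frame-projected read (complete codons only). Reads
below a 50% identity floor are "unassigned" rather than force-fitted.

The keep rules are: **pass** = no stops, no frameshifts, no inserted
codons, fewer than four deleted codons; **repaired** = exactly one
frameshift and nothing else, with the codon containing the frameshifted
position removed entirely (the indel's position within the codon cannot
be known, so the whole codon goes). Repaired output is trimmed to
complete reference codons, hence always length ≡ 0 (mod 3) and
stop-free — both invariants are asserted on every repaired read in the
tests. Every other read is discarded under the first violated rule in
the fixed order stop → frameshift → insertion → deletion, so each read
has exactly one verdict. Two tie rules are deterministic and worth
knowing: an insertion falling on a codon boundary is attached to the
codon on its 3' side, and an indel ambiguous within a homopolymer is
placed where the aligner puts it (effectively leftmost) — the repair
removes the same codon either way.

### Chimera screen

The screen compares the best *single-parent* identity of a read with
the best *two-parent* identity (prefix of one reference spliced to the
suffix of another at one breakpoint, both segments ≥ `min_segment` =
30 nt). The score is the identity gain on the whole read. The key
structural fact is that a non-chimeric read cannot gain: the best
single parent is itself an admissible "pair", so clonal reads score
exactly 0 and the threshold only has to clear noise. The default
`min_score_gain = 0.02` was calibrated against the canonical
construction — a half-and-half splice of two 10%-divergent parents at
L ≈ 313 yields a gain of ≈ 0.05, while a minority segment of 50 nt at
10% divergence yields ≈ 0.016 — so 0.02 detects balanced chimeras with
a wide margin and mid-sized segments reliably, while remaining an
order of magnitude above the per-read noise floor. A corollary worth
stating plainly: chimeras whose minority segment is very short carry an
intrinsically small signal (segment length × parent divergence / read
length) and no single-breakpoint detector can separate them from point
noise; the synthetic generator therefore plants breakpoints in the
central third of the insert, and the measured ≥ 95% sensitivity applies
to that regime, not to terminal-breakpoint chimeras.

## OTU pipeline

Clustering is deterministic greedy centroid clustering: dereplicate,
order by abundance (ties lexicographically), and let each sequence join
the *first* centroid within the dissimilarity radius, else found a new
one. This is a behavioral, not algorithmic, stand-in for Bayesian
clustering of natural sequence groups; the default radius 0.07 is the
midpoint of the 6–8% dissimilarity band used to calibrate such
clustering for marine invertebrate COI. Identity is matches / alignment
columns under global alignment with end-gap columns excluded — stated
explicitly because published "% similarity" figures rarely pin down the
denominator, and BLAST-style local identity differs subtly.

Taxonomy: best identity ≥ 0.98 (inclusive — "at least 98%") assigns the
best hit's species. Below that, a banded rank consensus stands in for
phylogenetic Bayesian assignment: the applicable band is the highest
floor at or below the best identity (defaults ≥0.95 genus, ≥0.90
family, ≥0.85 order, ≥0.80 class, ≥0.70 phylum — toolkit defaults, not
published values), and the assignment is the finest rank, starting at
the band's rank and coarsening, at which *all* hits within the band
agree. Below the lowest floor the query is unidentified. Assignment
rank is monotone in identity, a property the tests check. Diet tables
then remove OTUs whose species-level assignment equals the host
predator of a sample they occur in, and summarize occurrence (in 1 / 2
/ >2 individuals per predator species; cross-species sharing as the
fraction of a species' OTUs seen in at least one other predator).

Rarefaction uses the exact hypergeometric expectation
$E[S(d)] = \sum_i (1 - \binom{N-n_i}{d}/\binom{N}{d})$ computed with
log-binomials; the tests pin it to exhaustive enumeration on a toy
vector, to Monte-Carlo subsampling within three standard errors, and to
the vegan implementation as an independent cross-check.

## Synthetic data: what it emulates, and what it does not

The generators produce the study-shaped inputs the pipeline consumes:
12 species diverged ≥ 12% between and ≤ 2% within species (disjoint
per-species mutation strata make inter-species divergence additive and
therefore guaranteed), codon-structured stop-free barcodes of 220
codons, whose window 346–660 serves as the in-frame QC reference and
whose positions 346–658 form the 313 nt amplified insert; 16 one-gut
samples tagged hierarchically (4 MIDs × 5 tags); ~30% predator
contamination per sample; and a planted anomaly mix of 10% stop-codon
mutants, 10% single frameshifts (homopolymer-adjacent ±1 indels, the
dominant pyrosequencing error mode), 5% four-codon deletions and 1%
two-parent chimeras with central-third breakpoints. Sequencing noise is
opt-in (`substitution_rate`, `homopolymer_indel_rate`, both default 0):
the planted-verdict agreement criterion is defined at zero noise, where
truth labels are exact. Problem sizes in the test suite — 5,040 reads
for verdict recovery, 36 references for clustering, 100 + 100 reads for
the chimera criterion — were chosen as the smallest sizes at which the
binomial margins of the stated thresholds (99% agreement, 95%
sensitivity) are meaningful.

What the simulations do *not* emulate, and hence what passing tests do
not show: flowgram-space error structure (no `.sff` simulation),
digestion bias and copy-number variation between prey taxa, PCR
amplification bias and primer-template interaction during cycling,
reference databases with missing or mislabeled lineages, and the deep
unevenness of real gut-content communities. Results on real 454/Illumina
gut data will be worse than the synthetic recovery rates in ways these
tests cannot quantify.

## Known limitations

- Annealing is purely combinatorial; two primers with equal mismatch
  counts can have very different melting behavior.
- The chimera screen models one breakpoint and two parents;
  multi-breakpoint chimeras are only flagged if a single breakpoint
  already explains enough of the read.
- Greedy clustering is order-deterministic but, like all
  fixed-radius methods, can split taxa with deep intraspecific
  variation or lump recently diverged sisters; the radius is a
  parameter, not a promise.
- Rank-consensus taxonomy inherits the reference database: a congener
  missing from the references silently promotes a genus-level call to
  species level.
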