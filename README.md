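# minicoi

Degenerate-primer design and read processing for COI mini-barcode
metabarcoding.

The 658 bp "Folmer" fragment of mitochondrial cytochrome c oxidase
subunit I (COI) is the standard animal barcode, but it is too long and
too variable for degraded templates such as gut contents or
environmental DNA. A practical alternative is a *mini-barcode*: a
degenerate internal primer placed at a relatively conserved site inside
the barcode (positions 320–345), paired with an established flanking
primer to amplify a 313 bp fragment that still carries most of the
species-level signal. `minicoi` implements the computational side of
that strategy end to end, for molecular ecologists building or
evaluating COI metabarcoding workflows:

- **Primer algebra** — IUPAC base sets (including inosine), reverse
  complement, fold degeneracy `∏ per-position |base set|`, degenerate-site
  counts, bounded expansion to concrete oligos. The ten published COI
  primers (LCO1490/HCO2198, their dg/jg versions, Uni-Minibar,
  mlCOIintF/mlCOIintR), three predator blocking primers and the five
  6-bp sample tags ship as fixtures.
- **Conserved-site discovery** — per-column Shannon entropy
  `h(x) = −Σ f·log2 f` (bits) over a barcode alignment, ambiguity
  distributed fractionally; ranked conserved-window search; degenerate
  consensus primers covering every base above a frequency floor;
  3'-blocked (Spacer-C3) predator blocking primers that overlap a
  universal priming site and extend into predator-specific sequence.
- **In-silico PCR** — IUPAC set-intersection annealing (gapless, no
  position weighting), binding-site search on both strands, amplicon
  geometry, per-group mismatch-distribution reports.
- **Read QC** — hierarchical demultiplexing (MID + 6-bp tag, exact;
  primer regions tolerate ≤ 2 mismatches), a 150 nt length floor,
  reading-frame classification against in-frame references under the
  invertebrate mitochondrial code (stop codons, frameshifts, whole-codon
  indels), repair of single-frameshift reads by removing the affected
  codon, and a two-parent chimera screen.
- **OTU pipeline** — deterministic greedy centroid clustering at a 7%
  dissimilarity radius (midpoint of the 6–8% band used for marine
  invertebrate COI), identity-threshold taxonomy (≥ 98% ⇒ species,
  inclusive; banded rank consensus below), predator-self OTU removal,
  intra/inter-specific diet sharing tables, analytic rarefaction
  `E[S(d)] = Σ_i (1 − C(N−n_i, d)/C(N, d))`.
- **Synthetic data** — seeded generators for codon-structured reference
  panels, entropy-profiled alignments with planted conserved windows,
  and tagged gut-content read sets with exhaustive truth labels, so the
  whole pipeline is testable offline.

The alignment inner loop (affine-gap Gotoh, end-free reference mode) is
implemented in C++ via Rcpp.

## Worked example

```r
library(minicoi)

## primer arithmetic for the printed reverse mini-barcode primer
coi_primer("mlCOIintR")
#> <degenerate_primer> mlCOIintR (reverse)
#>   5'-GGRGGRTASACSGTTCASCCSGTSCC-3'  length 26, degeneracy 128, 7 degenerate site(s)

## in-silico PCR on a synthetic template realizing the mini-barcode
## geometry (forward site at barcode positions 320-345 of a 658 bp
## Folmer region)
tpl <- synth_folmer_template(seed = 1)
amplify(coi_primer("mlCOIintF"), coi_primer("jgHCO2198"),
        tpl$template, max_mismatches = 0)[ ,
        c("forward_end", "reverse_start", "insert_length")]
#>   forward_end reverse_start insert_length
#> 1         370           684           313

## a small simulated gut-content run: 4 samples x 100 tagged reads with
## planted anomalies (10% stop mutants, 10% single frameshifts,
## 5% four-codon deletions, 1% chimeras)
spec  <- sim_spec(seed = 1, n_samples = 4, reads_per_sample = 100)
panel <- make_reference_panel(spec)
sim   <- make_gut_reads(spec, panel)
qc <- run_read_qc(sim$reads, sim$scheme,
                  coi_primer("mlCOIintF"), coi_primer("jgHCO2198"),
                  panel$qc_references,
                  chimera_references =
                    panel$qc_references[!duplicated(panel$species)])
str(qc$summary)
#> List of 12
#>  $ input             : int 400
#>  $ pass              : int 283
#>  $ repaired          : int 50
#>  $ discard_chimera   : int 2
#>  $ discard_stop      : int 39
#>  $ discard_frameshift: int 0
#>  $ discard_insertion : int 0
#>  $ discard_deletion  : int 26
#>  $ discard_primer    : int 0
#>  $ discard_length    : int 0
#>  $ unassigned        : int 0
#>  $ final             : int 333
```

The accounting mirrors a metabarcoding run report: of 400 input reads,
283 pass untouched, 50 single-frameshift reads are repaired (their
output is always in frame and stop-free), and the stop-codon /
four-codon-deletion / chimera plants are discarded under the matching
verdict. Clustering the 333 retained inserts and assigning taxonomy
against the panel recovers the simulated community exactly:

```r
kept <- qc$records$verdict %in% c("pass", "repaired")
otus <- cluster_otus(setNames(qc$records$output_sequence,
                              qc$records$read_id)[kept], radius = 0.07)
otus
#> <otu_set> 12 OTUs from 333 reads (radius 0.070)
asn <- assign_taxonomy(otus, setNames(panel$inserts, names(panel$sequences)),
                       panel$lineage)
table(asn$method)
#> species_match
#>            12
```

All 12 simulated species come back as exactly one OTU each, every one
matched at species level (≥ 98% identity).

## Documentation

The methods vignette (`vignettes/minicoi-methods.Rmd`) describes the
models, parameter choices and limitations; every exported function has
roxygen documentation.
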