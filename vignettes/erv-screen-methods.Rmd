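---
title: "Screening paired genomes for conserved ERV-derived genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening paired genomes for conserved ERV-derived genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endogenous retroviruses (ERVs) litter vertebrate genomes with thousands of
decaying protein-coding relics. Occasionally one is *domesticated*: the host
keeps an ERV-derived open reading frame intact under purifying selection and
it becomes a functional gene (syncytins, ASPRV1, PEG10 are classic cases).
Finding such genes in a pair of related genomes is a filtering problem: the
signal (a handful of conserved ORFs) sits under a vastly larger background of
(i) young ERV copies that are intact merely because they are young, and
(ii) random stop-free stretches of genomic sequence.

`ervscreen` implements that filter as a reusable, fully testable pipeline:

1. **ORF harvest** — all stop-to-stop runs of at least 240 nt (80 codons) in
   all six reading frames of both genomes.
2. **Domain scan** — translated ORFs are scored against retroviral
   protein-domain profile HMMs; only ORFs with a hit at E < 1e-5 continue.
3. **Young-ERV removal** — greedy clustering at 50% amino-acid identity per
   species; clusters with more than ten members are discarded wholesale.
   Young ERV families are high-copy and near-identical, so they form large
   clusters; domesticated genes are low-copy and survive.
4. **Cross-species pairing** — best-hit local protein alignment of species-A
   ORFs against species-B ORFs at E < 1e-50 and a bitscore cut
   (default 200 bits); each subject ORF is used at most once.
5. **Known-gene exclusion** — pairs overlapping an annotated gene on a
   user-supplied exclusion list, or similar (E < 1e-5) to a known-protein
   database, are removed: the screen is after *new* gene candidates.
6. **Lineage specificity** — each candidate peptide is searched against
   outgroup genomes (translated search). A hit only counts as a putative
   ortholog when it covers at least 60% of the query *and* lies within 1 Mb
   of the conserved neighbour ("marker") gene on the same contig; remote
   RT-like hits are just other ERV copies.
7. **Characterisation** — Nei–Gojobori dN/dS with the codon-based Z-test of
   neutrality per pair, a neighbor-joining tree of the candidate peptides
   (duplication-before-speciation topology test), a catalytic-motif check
   (`YXDD`), and a k-mer self-dotplot of the candidate locus for
   tandem-duplication evidence.

The interface is the exported functions (`run_screen()` over a
`screen_config()` does everything; each stage is also callable on its own),
plus a thin command-line wrapper in `inst/scripts/ervscreen.R`.

## Models and numerical choices

### Profile HMM scan

The scan uses a deliberately small, fully specified profile model rather
than the full HMMER architecture (the screen only needs a calibrated local
domain scorer):

* match emissions are column residue frequencies of the seed alignment,
  smoothed toward uniform with total pseudocount mass 1; columns with at
  least 50% residue occupancy become match states;
* insert states emit the background (overall seed composition, smoothed);
* transitions are position-independent
  (M→M 0.9, M→I = M→D 0.05, I→M 0.6, D→M 0.7) and are scored as
  `log2(t / t_MM)`, so the all-match path carries zero transition cost;
  entry into and exit from any match state are free. A profile's score
  against its own consensus is therefore exactly the summed per-position
  emission log-odds — a property the test suite exploits;
* `X` and other non-standard residues score 0 bits (background).

Viterbi (maximum-scoring path) scoring is used rather than Forward; the
threshold semantics are preserved by calibration: each profile is scored
against `n_random = 1000` background-sampled peptides of length 400 and a
Gumbel null is fitted by the method of moments
(`lambda = pi / (sd * sqrt(6))`, `mu = mean − gamma/lambda`). E-values are
`N_seqs × P(S ≥ s)`. The tests verify the Viterbi kernel bit-exactly against
exhaustive path enumeration for all peptides up to length 6 over a reduced
alphabet, and verify Gumbel parameter recovery on synthetic draws.

### Alignment and E-values

Pairwise protein alignment (local, global and free-end-gap) is BLOSUM62
with gap open 11 / extend 1 throughout, computed by
`Biostrings::pairwiseAlignment`. Karlin–Altschul parameters are fixed at
the published gapped-BLOSUM62 values λ = 0.267, K = 0.041: E-value *parity*
with NCBI BLAST is a non-goal, threshold semantics are what matter, and
both constants are configurable in `scoring_scheme()`. Clustering identity
uses the CD-HIT convention — identical residues in the best free-end-gap
global alignment divided by the shorter sequence length — and membership is
tested against cluster representatives only (greedy incremental
clustering), which is faithful to the cited tool but weaker than
single-linkage; users expecting the latter should know large families can
in principle split. Translated search operates on stop-split six-frame
segments and is not frameshift-tolerant. Query cover is the aligned query
span over the query length, which keeps cover in (0, 1] even for gapped
alignments.

### Selection statistics

`nei_gojobori()` implements the 1986 counting method: per-codon synonymous
site fractions (changes to stop codons excluded from the per-position
denominator), pathway-averaged difference counts over all orderings of the
differing positions (orderings through stop codons excluded; if every
ordering passes through a stop, the average falls back to all orderings),
and Jukes–Cantor correction `d = −(3/4) ln(1 − (4/3) p)`. Proportions at or
above 3/4 are flagged undefined rather than raising errors.

The codon-based Z-test follows the MEGA convention:
`Z = (dS − dN)/sqrt(Var(dS) + Var(dN))` with variances estimated by a
seeded bootstrap over codon columns (1000 replicates by default). Two
properties matter in practice:

* the formula ignores the covariance of dS and dN, which makes the
  one-sided test mildly conservative (measured rejection ≈ 0.034 at
  α = 0.05 under the null);
* NG86 itself is biased when the mutation process has transition/
  transversion bias: transitions are enriched for synonymous changes, so
  with ts/tv κ ≈ 2 the method reports dS > dN even for neutrally evolving
  sequence. The test-suite calibration experiment therefore simulates the
  null with κ = 1 (the estimator's own model); results on κ-biased data
  should be read with this known NG86 limitation in mind. The modified
  (ts/tv-weighted) NG86 variant is out of scope.

Codon pair alignments are built by globally aligning the two translations,
back-threading codons, and dropping every column with a gap, stop or
ambiguous base.

### Tree test

The duplication-before-speciation claim is tested with Poisson-corrected
peptide distances (`d = −ln(1 − p)` over shared ungapped columns) and
canonical Saitou–Nei neighbor joining (`ape::nj`); negative branch lengths
are clamped to zero with the deficit moved to the sibling branch. A
gap-fraction column filter (threshold 0.5) stands in for heavier alignment
trimming. Maximum-likelihood inference and bootstrap support are
deliberately out of scope — NJ on an additive matrix is exact (the tests
verify a hand-built additive matrix round-trips to nine decimals), and the
monophyly question the pipeline asks does not need branch support.

## The synthetic data generator

`simulate_screen_fixture()` builds the study conditions every end-to-end
test and the acceptance script run under. Defaults (all in `sim_config()`):

| parameter | default | meaning |
|---|---|---|
| contigs | 150 kb + 100 kb | per species, uniform ACGT background |
| young family | 30 copies, 98% identity | 2 kb elements, 1500-nt ORF from a gag-like seed |
| domesticated genes | 3 tandem copies | 1800-nt ORFs, opposite strand of the marker intron |
| dN/dS (domesticated) | 0.1 | purifying selection on the planted genes |
| paralog dS | 0.5 | divergence accrued between tandem copies before speciation |
| pairwise dS | 0.15 | synonymous divergence between the two species |
| ts/tv | 2.0 | transition/transversion rate ratio |
| marker gene | 2 × 900 nt exons, dN/dS 0.05 | the conserved neighbour anchoring proximity tests |
| outgroup | branch dS 0.5, no ortholog | carries the marker and a far, unrelated RT copy |

Design points worth knowing:

* **Divergence semantics.** `branch_length_syn` is the expected *pairwise*
  synonymous divergence between the two species on the Nei–Gojobori scale;
  each branch receives half. The proposal rate of the codon-evolution
  engine is calibrated from the sequence's codon composition and the
  κ-weighted synonymous proposal fraction, so the configured value lands on
  the dS scale the estimator reports (measured recovery: median dS 0.148 at
  configured 0.15).
* **Codon evolution by rejection sampling** of single-nucleotide proposals:
  synonymous proposals always accepted, nonsynonymous with probability ω,
  stop-creating never. No rate-matrix integration; the bias is negligible
  at the configured divergences (dS ≤ 0.5).
* **Indel-free evolution**, so truth-table coordinates lift over unchanged
  between the ancestor and both species — coordinates in the emitted GFF3
  exactly index the planted sequences.
* **Young copies decay realistically**: each copy is an independently
  mutated descendant of a master element, so some copies acquire chance
  nonsense mutations and contribute ORF fragments instead of full ORFs.
  All of them still cluster with the family and are removed together.
* The domesticated ORFs carry a diverged copy of the RT seed consensus with
  the catalytic `YxDD` aspartates ablated (to `YVAA`) by default, matching
  the motif-absence check in the report.
* The marker gene's tandem array sits in a single intron on the minus
  strand, with the spacer duplicated along with the ORF — so the
  self-dotplot of the locus shows bands at exactly one and two unit
  lengths (unit = ORF + 6 nt of stops + spacer).

What the generator does **not** emulate: real repeat landscapes, LTR
structure (gag/pol/env architecture), GC heterogeneity (GC is configurable
but uniform), indels, segmental duplications, assembly gaps beyond `N`
runs, and annotation noise. Passing the end-to-end tests therefore shows
the decision logic is correct under clean, truth-known conditions; it does
not show robustness to the full messiness of real assemblies, where
threshold tuning (especially the bitscore cut and the proximity radius)
matters.

## Problem sizes and reproducibility

All simulation scales were chosen to keep each experiment statistically
meaningful at desk scale: the default fixture uses 250 kb per species;
replicated experiments (Z-test calibration: 500 replicates of 300 codons;
power and monophyly: 100 replicates; estimator recovery: 50 replicates of
the reduced 46-kb configuration) use the smallest sizes at which the
measured quantities are stable. Every stochastic step is seeded:
generator output is a pure function of `(sim_config, seed)`, bootstrap
p-values are bit-reproducible, and `run_screen()` re-runs identically from
the resolved configuration echoed to `config_echo.yml`.

## Known limitations

* The bitscore cut for cross-species pairing is under-determined by the
  screen's design; both a fixed default (200 bits) and a largest-gap
  automatic mode are provided, and the choice is logged.
* Pairing is one-directional best-hit (A queries against B subjects), as in
  the screen's design; strict reciprocal-best-hit is not enforced.
* The proximity radius (1 Mb) conservatively separates intronic/adjacent
  loci from distant paralogs; on highly fragmented assemblies the
  "different contig" branch will dominate and weaken the test.
* E-values from both the HMM scan and the Karlin–Altschul formula are
  calibrated approximations; they order hits correctly but are not
  exchangeable with HMMER or BLAST output.
* NG86/Z-test caveats under ts/tv bias, described above.
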