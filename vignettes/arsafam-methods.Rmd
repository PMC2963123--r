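---
title: "Methods: congruence, context, and motif analysis of ArsA-family ATPases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: congruence, context, and motif analysis of ArsA-family ATPases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsafam)
```

## Scope and model

`arsafam` asks, for a family of ATPases (ArsA and its homologues) and a
candidate partner family (a transporter such as ArsB, Acr3, ArsP, or CstA, or
an accessory protein such as ArsD or CstX), two questions a comparative
genomicist can answer without wet-lab data:

* **Context**: across a set of annotated genomes, is the partner family
  encoded in the *same operon* as the ATPase, *elsewhere in the genome*, or
  *absent*?
* **Coevolution**: restricted to members encoded in the same operons, are the
  two families' phylogenies congruent?

Coevolution plus persistent co-operonic context is read as evidence of
cofunctioning; congruence alone is not proof (promiscuous partners are known
to cofunction without coevolving), and the package reports statistics, never
biology.

## The homologue catalog

The packaged catalog (212 proteins, 18 clusters) records abbreviation,
organism, size, organismal type, accession string, and cluster. Summaries
report the member count, the arithmetic mean size rounded **half-up** to an
integer, and the maximum size. Half-up is deliberate: cluster 12's sizes
average 360.5 and cluster 14's 326.5, and the integer averages conventionally
reported for them (361 and 327) require rounding halves upward; R's default
banker's rounding would disagree. One known discrepancy is preserved rather
than repaired: the mean of the catalog's cluster 10 sizes is 419, while the
prose figure circulated for that cluster is 410. `summarize_cluster()`
reports the catalog-derived 419; the acceptance suite asserts the
disagreement instead of forcing a match. Cluster membership also fixes the
domain architecture: clusters 1, 4, and 6 are double-domain (~600 aa)
proteins, all others single-domain.

## Redundancy filtering

`filter_redundant()` emulates a 90% identity screen with a deterministic
greedy rule: candidates are visited longest-first (ties by name), and a
candidate is dropped if it matches an already-retained sequence at or above
the cutoff, or is a fragment (shorter than `fragment_fraction = 0.6` of a
retained sequence while matching it over the aligned region). Identity is
computed over alignment columns *excluding terminal gaps*, so fragments are
judged on their overlap. The historical tool this emulates did not publish
its exact criteria; whether it measured identity over the shorter sequence or
the whole alignment is unknowable, and this implementation's choice is a
documented surrogate, not a reconstruction.

## Alignment and distances

Pairwise alignment is classical Needleman–Wunsch with affine gaps (a gap of
length L costs `open + L·ext`), BLOSUM62, open 11 / extend 1 — community
defaults adopted because the original analyses delegated alignment to an
external program whose 2010-era parameters are unrecorded. Ties in the
dynamic program are broken match > gap-in-B > gap-in-A, making output
deterministic. The test-suite checks the DP against exhaustive enumeration of
all alignments for sequences up to length 4.

Distances feeding tree construction are Poisson-corrected identities,
`d = −ln(identity)`, capped at 10 when identity is 0 (with a warning). A
score-based alternative, `d = 1 − S(a,b)/max(S(a,a), S(b,b))`, is provided
for bit-score-style family trees. Multiple alignment is progressive:
NJ guide tree on Poisson distances, profile–profile merging in postorder
under the sum-of-pairs score with gaps contributing zero substitution score.
No iterative refinement is attempted (a stated non-goal).

Coordinates: residue positions are 1-based in ungapped reference sequences
(so "C113" means the 113th residue), alignment columns are 0-based.

## Neighbor joining

`neighbor_joining()` is the classical agglomerative algorithm: join the pair
minimizing `Q_ij = (r−2) d_ij − R_i − R_j`, assign branch lengths by the
two-point formulas, reduce, finish with the three-point formulas. Two
numerical policies: Q-ties are broken lexicographically by the smallest taxon
id in each candidate subtree (determinism), and negative branch estimates are
clamped to zero with the deficit moved to the sibling branch so the joined
pair's path length is preserved. Distance comparisons in tests use an
absolute tolerance of 1e-9. On additive matrices NJ is exact; the acceptance
suite verifies topology (RF = 0) and patristic recovery at 1e-9 on 100
random additive cases up to 8 taxa.

## The congruence test

Visual tree comparison is formalized as:

* `robinson_foulds()` — both trees pruned to the paired leaves, B relabeled
  to its partners, symmetric difference of non-trivial bipartitions;
  normalized by `2(n−3)`.
* `cophenetic_congruence()` — Pearson correlation of matched patristic
  distances (mirror-tree statistic); scale-invariant, so overall rate
  differences between families do not matter.
* `permutation_test()` — null distribution by shuffling the B side of the
  pairing; `p = (1 + #{null ≥ obs})/(n_perm + 1)`; verdict `coevolved` at
  `p ≤ 0.05`, `inconclusive` when a patristic vector is degenerate (star
  trees). At least 5 pairs and 99 permutations are required.

The alpha of 0.05 and the choice of the cophenetic statistic as primary (RF
reported alongside) are this package's formalization; the analyses it
emulates judged congruence by eye, and their implicit threshold is
undefined. Verdicts on real data should be reported with the statistic, not
coerced to match prose expectations.

**Paralogues.** When an operon offers several candidate pairs,
`select_best_pairing()` enumerates the per-operon combinations and returns
the pairing maximizing the observed correlation, flagged `post_hoc = TRUE` —
it is a best-case bound, not an unbiased estimate, and the flag exists so
downstream reporting can say so. Partners encoded in the same genome but not
the same operon follow the `Aaa1-2E` ("elsewhere") naming convention via
`context_leaf_name()`; `operon_pairing()` itself never emits `E` names.

## Genome context

Operon predictions from a curated database are not reproducible offline, so
`call_operons()` uses the standard prokaryotic surrogate: maximal runs of
same-strand genes with intergenic gaps ≤ 200 bp (configurable), overlapping
genes kept together, every gene in exactly one operon. Coordinates are
1-based inclusive. `association_profile()` then classifies each genome
containing family A into `same_operon` / `elsewhere_in_genome` / `absent`
(a partition — the three counts always sum to the number of family-A genomes
after exclusions), with an `exclude` set implementing "… but family X is
nowhere in the genome" bookkeeping. Historical instance counts (e.g. "33
instances in 28 bacteria and archaea") depended on a 2010 database snapshot
and are deliberately out of reach; the module reproduces the bookkeeping,
not those numbers.

## Motif discovery

`discover_motif_em()` is an OOPS (one occurrence per sequence) EM: posterior
over start positions against a 0-order background, frequency re-estimation
with pseudocount 0.01 per cell, convergence at max frequency change < 1e-6
or 500 iterations, best of `n_starts` seeded restarts by log-likelihood. Two
implementation notes:

* The monotonicity assertion applies to the *penalized* objective
  (likelihood plus the Dirichlet pseudocount prior) — that is the quantity
  MAP-EM provably never decreases.
* EM on planted motifs reliably converges to an off-by-one *phase shift* of
  the truth; after each restart the MAP starts are slid ±1..3 columns,
  re-estimated, and re-converged until no shift improves the likelihood.
  Without this step roughly a tenth of planted-motif runs return a shifted
  consensus.

Information content per column is the KL divergence to the background in
bits: at most `log2 20 ≈ 4.32` under a uniform background (more if the
background is estimated from input and the motif residue is rare there).
Logo letter heights are `IC × frequency`, summing per column to the column
IC. Zero-or-more and multi-occurrence motif models are out of scope:
the motifs of interest here (P-loop, DTAP) occur once per ATPase domain, and
double-domain sequences should be split at the inter-domain linker before
training, consistent with reporting "the motif for the first halves".

`motif_match()` scans degenerate patterns (`X` wildcard, `[TS]` or `(T/S)`
alternatives) and returns all overlapping hits.

## Hydropathy

Kyte–Doolittle residue values, centered moving average, default window 19
(the standard transmembrane-scan setting; ends carry `NA`).
`average_profiles()` adds alignment-averaged hydropathy, an α-helical
amphipathic moment (100° per residue, per-window normalized), and a
similarity track (modal-residue frequency). `predict_tms()` reports maximal
runs of window centres above threshold 1.6 of length ≥ 15, merging runs
separated by < 4 positions; because these are *window centres*, a 21-residue
hydrophobic helix yields an interval of about 15 positions inside the helix,
not the full helix extent. The 1.6/15 defaults make the constructed
8-helix test fixture unambiguous and are fully configurable; they are a
surrogate for unpublished internals of the historical plotting tools.

## Synthetic data: the stated world

The simulators generate data with exactly the structure the tests assume:

* `random_tree()` — random topology with i.i.d. exponential branch lengths,
  mean 0.3 substitutions/site. (A Yule-style pure-birth process motivates
  the shape; the implementation uses `ape`'s random-split topology, which
  serves the same purpose — creating realistic tree signal — without
  modelling a birth clock.) Labels are assigned to tips *uniformly at
  random*: tip numbering follows cladewise order, and inheriting it would
  correlate label order with tree position, which across two independent
  trees correlates the identity pairing and silently inflates the
  congruence test's type-I error several-fold. This is the single most
  load-bearing detail in the generator.
* `evolve_sequences()` — Poisson substitution (`P(sub) = 1 − exp(−rt)` per
  site per branch), replacement drawn from background excluding the current
  residue, optional invariant-site mask, no indels and no rate matrix. This
  is deliberately simpler than real protein evolution: adequate for
  distance/tree recovery and calibration tests, silent on alignment
  difficulty, rate heterogeneity, and compositional bias — so a green test
  establishes the statistics work on clean signal, not that the pipeline is
  robust to real-data pathologies.
* `simulate_coevolving_pair()` — shared mode: one topology, B's branch
  lengths jittered per branch by `exp(N(0, σ²))` with σ = 0.1 as the stated
  coevolution condition; independent mode: two unrelated topologies
  (null condition). Defaults: 12 taxa, 300-residue roots, rate 1.
* `simulate_genomes()` — operon templates mirroring the three genomic
  contexts of the family (`arsR-arsD-arsA-arsB`, `arsR-arsA-acr3`,
  `arsA-cstA-cstX-cstY`, `gvpN-gvpL-gvpF-arsA`), intra-operon gaps ≤ 100 bp
  against a calling threshold of 200 bp, 10 kb inter-operon spacers,
  "elsewhere" placements on a second contig. The generator keeps its own
  truth record (planted operons, per-genome association classes, planted
  pairings) computed from the plant, never by calling the modules it is
  meant to test.

Calibration measured against this world (all seeds pinned in the acceptance
suite): congruence power 50/50 at σ = 0.1 with 12 pairs; type-I 10/200 at
nominal 5%; planted `DTAPTGHTIRLL` recovered 20/20.

## Design decisions that were genuinely open

* **Acceptance reporting.** The artifact's acceptance-target list is empty;
  all acceptance substance is property-based and executable, so
  `scripts/acceptance.R` emits an empty JSON object after an end-to-end
  smoke run rather than inventing numeric targets.
* **Criterion granularity for power/size.** The congruence calibration runs
  at tree level (generating trees, no sequence evolution) exactly as the
  module contract states it; the full sequences → distances → NJ → test
  route is exercised separately at 50 + 50 replicates with 200-residue
  roots to stay within test-time budgets. Both are seeded and
  deterministic.
* **Buy vs build.** FASTA I/O and BLOSUM62 come from Biostrings, tree
  containers/Newick/patristic distances from ape, and the RF count inside
  `robinson_foulds()` from phangorn — infrastructure with decades of
  scrutiny. The alignment DP, NJ, the permutation test, operon logic, EM,
  hydropathy, and the simulators are implemented here, because they carry
  the analysis. Each bought primitive is cross-checked in the test-suite by
  an independent oracle (brute-force alignment enumeration, brute-force
  bipartition sets, additivity identities).

## Known limitations

* Real-database instance counts and real-sequence tree topologies are not
  reproducible offline and are not attempted.
* The progressive aligner has no iterative refinement; deep or gappy
  families will align worse than with modern MSA tools.
* The OOPS motif model cannot represent absent or repeated occurrences
  within one (single-domain) sequence.
* The TMS caller is a threshold heuristic, not a topology model; signal
  peptides and re-entrant loops are out of scope.
* The redundancy filter is a surrogate for an unpublished historical tool;
  retained sets are deterministic and well-defined but not byte-identical
  to the original's.
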