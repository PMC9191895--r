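---
title: "Mining secreted peptide families: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining secreted peptide families: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfam)
```

# The problem

Short secreted signalling peptides are among the hardest gene families to
catalogue. Their precursors are under 150 residues, sequence conservation
is concentrated in a handful of positions (often a disulfide-forming
cysteine pair), and a large fraction of family members are simply missing
from reference annotations. `pepfam` packages the complete discovery
procedure — expression screen, iterative profile search, similarity-network
community selection, six-frame genomic rescue, motif refinement, and
phylogeny — so that each stage is a tested, parameterized function and the
whole chain can be benchmarked against planted ground truth.

This vignette documents the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic benchmark does and
does not demonstrate.

# Stage models and parameters

## Expression screen

`screen_short_secreted()` keeps proteins **strictly shorter than 150
residues** (a 150-residue protein is excluded) with a positive
signal-peptide call, ranked by descending log2 fold-change in the chosen
elicitor/timepoint column. Induction is a *rank*, not a threshold: the
biological screen this models selected candidates from the top of the
list, so an optional `min_log2fc` cut exists but defaults to off.
Candidates without an expression row — the common annotation-gap case — are
kept with `NA`, sorted last, and reported, because losing them silently
would defeat the purpose of the later genomic rescue.

## Pairwise alignment

`local_align()` is an affine-gap Smith–Waterman (three-state dynamic
program, compiled): BLOSUM62 scores, gap open −11 covering the first gapped
residue, −1 per extension — the defaults of the fast aligners this step
stands in for. Traceback tie order is diagonal, then up, then left, and
the best cell is the first maximum in row-major order, so results are
fully deterministic. Percent identity is identical columns over all
alignment columns of the optimal local alignment; this is the quantity the
similarity network thresholds. `X` scores zero against everything
(background behaviour for ambiguity codes).

A deliberate consequence: two *unrelated* short proteins usually still
have a short, high-identity optimal local alignment, so identity
thresholds alone cannot separate family from background. The pipeline
never relies on them alone — community structure and the cysteine motif do
the discriminating.

## Profiles and E-values

`build_profile()` turns an alignment into a log-odds PSSM:
`p = (count + α·b)/(n + α)` per column with pseudocount weight `α = 1`
and a uniform background by default; columns below 50% occupancy are
dropped (the usual match-column heuristic). The full profile-HMM
machinery (position-specific transition probabilities) is intentionally
replaced by a PSSM with affine gaps — at the scale of curated candidate
sets this captures the same signal and keeps every score exactly
reproducible; this is the package's main fidelity gap relative to
HMM-based search tools, and it is a stated one.

Statistical significance is owned by one module. `calibrate_evalue()`
scores the profile against residue-shuffled database sequences and fits a
Gumbel distribution by the method of moments (`λ = π/(σ√6)`,
`μ = m − γ/λ`); `E = N · P(S ≥ s)` with `N` the number of targets
searched, so E-values are exactly linear in database size. Shuffling
preserves each target's length and composition, which makes the null
conditional on the database actually searched. Pooling targets of
different lengths leaves the fitted tail slightly conservative-to-neutral
(the acceptance suite checks that ~1 of 500 shuffled nulls reaches
E ≤ 1); per-length calibration was judged not worth the extra machinery at
these database sizes.

Default inclusion threshold for peptides is `E ≤ 1e-5`; the receptor
preset uses `1e-10`, mirroring the stricter thresholds conventional for
long, information-rich queries.

## Iterative search

Round one recruits by pairwise alignment against the seeds (identity ≥
20%, raw score ≥ 50 by default); each later round realigns the included
set, rebuilds and recalibrates the profile, and re-searches. The included
set grows monotonically and iteration stops at a fixpoint or after 5
rounds — the iteration count of the original jackhmmer-style search is
unstated, so fixpoint-or-5 is this package's choice, and the fixture in
the test suite demonstrates the behaviour the iteration exists for: a
member divergent enough to miss the pairwise cutoff is captured once the
profile has absorbed the family.

## Similarity network and communities

Edges connect candidates whose local-alignment identity is **strictly
above** the threshold (20% for peptides, 50% for receptors), weighted by
that identity; weighted modularity
`Q = Σ_c [Σin_c/(2m) − (Σtot_c/(2m))²]` is optimized by the package's own
two-phase Louvain: greedy local moves in a seeded-shuffled node order,
community aggregation, repeat until the gain drops below 1e-12. The
returned `Q` always equals an independent recomputation, per-pass `Q` is
non-decreasing, and on small graphs the optimum matches exhaustive
partition enumeration (tested). Only communities containing at least one
seed survive — this anchor is what lets the relaxed recruitment stay
permissive without flooding the family with background.

## Genomic rescue

`dna_rescue()` translates both strands in all three frames, enumerates
ATG→stop ORFs within the peptide length bounds (25–300 residues by
default), discards any ORF overlapping an annotated feature by ≥ 1 bp on
either strand (the conservative reading of "filter annotated genes"), and
scores survivors against the family profile. Gene prediction is
deliberately reduced to ORF extraction: the planted genes are intron-free
and, in the real procedure, the gene finder only formalized candidate
regions that the profile search had already localized. ORFs are sorted by
content before calibration so the rescue is *exactly* invariant under
reverse-complementing a genome — an invariant the test suite asserts
rather than assumes.

## Motif refinement

The family motif is two cysteines with 9–11 residues between them.
"Spacing" is implemented as the gap between *consecutive* cysteines
(equivalently the regex `C[^C]{9,11}C`), because the written description
does not say whether a third cysteine may sit inside the pair; the
index-difference alternative is available via `count_intervening_cys =
TRUE`. Length filters are inclusive at their bounds (≤ 300 for peptides,
≥ 500 for receptors). Manual curation is modelled as an explicit,
recorded exclusion list — irreproducible visual judgements become a logged
parameter.

## Domain callers

The SP/TM/LRR/kinase callers are transparent rule-based stand-ins for the
neural/HMM predictors used in practice, and no fidelity to those tools is
claimed. Signal peptide: ≥ 1 K/R in residues 1–5, an 8-residue window of
mean Kyte–Doolittle hydropathy ≥ 1.8 within the first 30, cleavage at the
first post-core position whose −3/−1 residues are small (A,G,S,C,T,V).
Transmembrane: 19-residue windows at mean hydropathy ≥ 1.6, merged, then
trimmed to the positive-hydropathy core — without trimming, window
merging over-extends boundaries by up to ~5 residues; with it, engineered
spans are recovered residue-exact. Topology is type-I (N-terminus
extracellular after the SP), appropriate for receptor kinases; the
ectodomain is the longest extracellular segment, ties N-terminal. Kinase:
the ordered motif chain GxGxxG → K (≤ 30 residues later) → HRD → DFG
(≤ 60 residues after HRD), positive at ≥ 3 of 4. LRR: sliding
LxxLxLxxNxL consensus scoring the five conserved positions (L/I/V/F
accepted at L positions), called at ≥ 4/5, greedy non-overlapping.

## Phylogeny, clades, logos

Distances are p-distances with pairwise gap deletion, Poisson-corrected
(`d = −ln(1−p)`, capped at 10 for saturated pairs). Trees are built by
canonical neighbor joining with lexicographic tie-breaking and negative
branch lengths clamped to zero (the deficit shifted to the sister
branch) — NJ is exact on additive matrices, which makes the tree stage
testable to machine precision, and stands in for approximate-ML tree
building at these sizes (a second stated fidelity gap). Clade extraction
defines a node's age as its maximum branch-length path to a descendant
leaf and takes maximal nodes with age ≤ cutoff; this yields a partition
of the leaves that only coarsens as the cutoff grows. The published
cutoffs (9 for peptides, 5.5 for receptors) are carried as presets with
the caveat that the original tool's branch-length units are not defined
anywhere in print — the semantics here ("age" as defined above) is this
package's documented assumption. Bootstrap support resamples alignment
columns without realignment. Logos trim columns seen in **fewer than 5%**
of sequences (a column at exactly 5% stays) and report
`IC = log2(20) − H` bits per column.

# The synthetic benchmark

`generate_benchmark()` produces the package's reference conditions: 8
species × 3 family members derived from one ancestor at 10% per-site
substitution (cysteines never mutate; signal-peptide positions mutate
within their residue class so the SP architecture survives), precursor
length 60–120 with a 25-residue signal peptide, the C-x(9–11)-C motif in
the C-terminal half of the mature region, 25% of members omitted from
proteome and annotation (present only in the genome, half of all genes on
the minus strand, a same-frame stop codon guarding each gene's upstream
frame so ORF extraction is interval-exact), 40 decoy short proteins per
species (half carrying the same engineered SP block, none carrying the
cysteine motif), and an expression table with family log2 fold-changes at
Normal(4, 0.5) against decoys at Normal(0, 0.5) — about five standard
deviations of separation, the regime where ranking screens are actually
used. Every generator is bit-reproducible under its seed.

Two design choices deserve emphasis. First, the generators and the
rule-based detectors are *co-designed*: planted signal peptides satisfy
the package's SP heuristic by construction, so 100% SP recall on planted
members validates the plumbing, not SignalP. Passing the benchmark
demonstrates that the pipeline's logic is correct, deterministic and
lossless under its stated conditions; it does not demonstrate performance
on real proteomes, where the predictors this package replaces are
substantially better than its transparent rules. Second, the unannotated
quota is a *global* count, `round(fraction × total members)`, spread at
most one per species in seeded order — per-species rounding would make a
25% fraction unrealizable with 3 members per species (0.75 rounds to 1,
i.e. 33%), and the benchmark's purpose is precisely that the discovered
unannotated fraction recover the planted one.

Problem sizes throughout the tests and the acceptance script (8×3
benchmark, 200 alignment-oracle pairs, 50 NJ trees at ≤ 16 taxa, 10,000
cysteine-filter sequences, 500 shuffled nulls, 100-replicate bootstrap
demonstrations) were chosen as the smallest sizes at which each property
is sharply distinguishable from noise.

# Degenerate inputs and numerical conventions

Coordinates are 1-based inclusive at every interface. Empty sequences
align with score 0; an all-gap alignment cannot form a profile; a
zero-variance null raises an error rather than a meaningless fit;
unrooted trees are rejected by clade extraction; a graph with no seeds in
it is an error ("empty family") rather than an empty result. Newick and
FASTA round-trips are identities, with branch lengths written at 17
significant digits so path-length properties survive serialization.

# Known limitations

* PSSM-with-gaps instead of full profile HMMs; NJ instead of
  approximate-ML trees; rule-based domain callers instead of trained
  predictors. All three are stated stand-ins chosen for exact
  testability.
* The mutation model is substitutions-only by default so mature-region
  coordinates stay aligned between truth and output; indel evolution,
  introns, realistic codon usage and non-star family phylogenies are out
  of scope of the generator.
* E-value calibration pools target lengths; at much larger database
  scales a length-conditional calibration would be warranted.
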