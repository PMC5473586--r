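---
title: "pirmkl: methods, parameters and design notes"
author: "pirmkl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirmkl: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter and why they default as they
do, what the synthetic-data generator emulates (and what it does not), the
numerical choices, and the known limitations. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The classification problem

A candidate sequence is described by far more than its nucleotide string:
where it maps, whether it maps in the company of other candidates, what
lies up- and downstream of it on the genome, and whether it can base-pair
with transposable elements. Each of these carries weak signal on its own
scale and type — binary bits, counts, bp distances up to tens of
kilobases, probability vectors, distance matrices. Kernels give these
heterogeneous descriptions a common currency: each feature family becomes
an N×N similarity matrix over the training sequences, and multiple kernel
learning (MKL) weighs the matrices against each other inside the SVM
training itself. A feature that fails to separate the classes in a given
dataset is down-weighted rather than poisoning a concatenated feature
vector — which is also what makes per-kernel accuracies readable as
feature pertinence.

## Kernels and their feature extractors

All twelve kernels are Gaussian, `k(x,y) = exp(-gamma * ||x - y||^2)`,
with the Euclidean distance for vector representations and the Frobenius
distance for the one matrix-valued representation (cluster context). The
extractors, with their defaults:

* **U1A10** — indicator bits for T at position 1 and A at position 10 of
  the stored DNA string (RNA is stored on the DNA alphabet; the 5' U test
  is a T test). Positions beyond the sequence end give 0.
* **KmerFreq / KmerPos** — 3,588 wildcard patterns (all strings over
  A,C,G,T,X for k = 1..5 whose wildcard fraction is at most 0.4; the bound
  is read as count(X)/k <= 0.4 per pattern, which reproduces that total).
  A supervised selector keeps `n_kmers = 32` of them; frequencies are
  overlapping match counts divided by sequence length, positions are
  1-based leftmost match offsets with 0 encoding absence (so absence is
  unambiguous). Selection uses the discriminative information of the
  kernel it serves: frequencies for KmerFreq, first positions for KmerPos.
* **TEbinding** — the sequence is slid against the reverse complement of
  each transposon target at every offset; aligned positions that can pair
  (Watson–Crick plus G·U wobble) are marked `(`. The bracket string of
  the best-scoring target (ties: first in input order; `binding_top_m`
  averages over the top m instead) is converted to 32 triplet elements —
  middle base × 2³ pairing states of a sliding 3-window — normalised to a
  probability vector. A plug-in interface accepts externally computed
  bracket strings (e.g. from a thermodynamic duplex predictor) keyed by
  sequence id, replacing the built-in engine entirely.
* **Cluster** — for `n_neighbors = 4` nearest training-set positions on
  the same chromosome (distance = |start − start|, strand ignored,
  labels never consulted), the (K+1)×(K+1) matrix of pairwise genomic
  distances, ordered target first then neighbours by increasing distance.
  The ordering convention is part of the contract because the Frobenius
  metric is ordering-sensitive. Missing neighbours and unmapped sequences
  are padded with a sentinel equal to the chromosome length; among
  multiple mapped positions the densest context (smallest neighbour
  distance sum) is used.
* **CentroTelo / Histone** — per track (centromere/telomere;
  H3K9me3/H3K27me3 peaks), the minimum edge-to-edge gap in bp between any
  of the sequence's positions and any track interval on the same
  chromosome; 0 when overlapping, chromosome length when the track is
  absent there.
* **AMyb** — the upstream flank (`d_promoter = 40000` bp, 5' side of the
  oriented sequence) is scanned for IUPAC consensus motifs; the closest
  match wins and is summarised as (motif length L, distance, 4^L /
  distance). The distance runs from the sequence 5' end to the motif 3'
  edge and is 1 when the motif is directly adjacent, so the score stays
  finite; with no match the vector is (0, D, 0). The motif set is an
  input; the default is a single synthetic 8-mer consensus placeholder,
  because the binding factor is known but its exact site is
  dataset-specific.
* **G4** — quadparser-style pattern `G{3+} ([ACGT]{1,7} G{3+}){3}` on the
  oriented window (±`d_g4 = 40000` bp), POSIX leftmost-longest, plus the
  C-run mirror for the opposite strand; features are the two nearest
  distances (same / opposite strand), the two counts, and the cumulated
  length pooled over both strands.
* **CpG** — upstream-only flank (`d_cpg = 20000` bp), sliding windows of
  100 bp advanced by 1; windows with GC >= 0.5 and observed/expected CpG
  (`count(CG)·len / (count(C)·count(G))`) >= 0.6 are merged when
  overlapping; merged spans shorter than `cpg_min_len = 100` are dropped
  and statistics recomputed on the merged span. Features: distance to the
  nearest island, count, mean O/E, mean length, mean C+G count.
* **TEflank** — per TE class (LINE, SINE, LTR), the cumulated copy
  identity (1 − RM − RD − RS from the annotation's mismatch / deletion /
  substitution ratios) and cumulated length of copies overlapping
  ±`d_te = 40000` bp, scaled by class weights defaulting to LINE 3,
  SINE 2, LTR 1 — LINEs are the class most enriched around piRNA
  clusters, then SINEs, then LTRs; the weights are user-configurable
  since no canonical values exist.
* **InvRep** — the oriented window (±`d_invrep = 40000` bp) is compared
  with its own reverse complement; gapless local alignments longer than
  20 bp with identity above 0.9 (both strict, as printed conventions) are
  found by exact 12-mer seeding and greedy ungapped extension, and
  summarised as (mean alignment length, cumulated matching bases).

Strand correctness is a tested invariant: reverse-complementing the genome
and mirroring every interval leaves all flank features unchanged, as does
translating a local context to a different chromosome offset.

## Bandwidth selection

Each kernel's gamma is data-driven. The Jaakkola heuristic
`gamma_J = 1 / (2 * median(D)^2)` uses the median of the off-diagonal
pairwise distances; the diagonal zeros are excluded (including them would
roughly halve the median on small sets and systematically inflate gamma),
while zeros arising from duplicated points are kept — unless they drive
the median itself to zero, in which case the median of the nonzero
distances is used as a guard. Nine candidates `exp(i) * gamma_J`,
i = −4..4, are evaluated by the inter-cluster distance delta — the mean
induced-space distance of each point to the opposite class mean, expanded
through the kernel trick

d(x, X̄)² = k(x,x) − (2/l) Σᵢ k(x,xᵢ) + (1/l²) Σᵢⱼ k(xᵢ,xⱼ)

(the class mean lives in the induced space; this expansion is the
normative definition). The gamma attaining the largest delta wins, ties
going to the smallest gamma (smoother kernel).

## The MKL optimiser

Weights live on the nonnegative unit L2 sphere — the smooth-weights
regularisation; sparse L1/Lp norms are out of scope. Training alternates
an exact C-SVM solve (kernlab's precomputed-kernel C-SVC; `C = 1` by
default) on K(w) with a projected-gradient step on w: by Danskin's
theorem, the gradient of the dual value is
`g_m = -1/2 (alpha∘y)' K_m (alpha∘y)`. Steps are spectral
(Barzilai–Borwein, clamped to [1e-8, 1e8]) with Armijo backtracking, so
the objective is non-increasing across accepted steps — we chose monotone
acceptance over a nonmonotone watchdog because each objective evaluation
costs an SVM solve and the monotone variant converges in a handful of
outer iterations at these problem sizes. Iteration stops when the
relative objective change falls below `tol = 1e-4` or after
`max_outer = 50` steps. Initialisation is uniform, `w = 1/sqrt(M)`; the
optimiser itself is deterministic.

## k-mer subset selection

Selecting 32 of 3,588 patterns is a combinatorial wrapper problem. The
default selector is a binary particle swarm (swarm 30, 50 iterations,
inertia 0.72, cognitive = social = 1.49, velocity clamp 4) whose particles
are repaired to exactly N active patterns (keep the N highest activation
probabilities, seeded-jitter tie-break); the fitness is the stratified
3-fold accuracy of a nearest-centroid classifier on the candidate columns
— a cheap wrapper whose folds are fixed per selection call so fitness
values are comparable across the swarm. Whether the original selection was
wrapper- or filter-based is not documented anywhere we could rely on, so
both are provided: `selector = "rank"` is a deterministic filter (top N by
absolute class-mean difference) useful for fast, exactly reproducible
pipelines; the wrapper is the default. Selection is the only stochastic
stage of training and is fully determined by its seed.

## Evaluation protocol

Stratified k-fold cross-validation (k = 5) with a seeded shuffle. All
supervised stages — k-mer selection, bandwidth selection, kernel weights,
the SVM — are refit inside every fold and only then applied to the
held-out fold; the original protocol does not spell out its leakage
handling, so we chose the conservative variant. The label-free per-
sequence extractions (flank scans, profiles, duplex folding) are computed
once and shared across folds, which is sound because they never see labels
or the fold split. Metrics are the five confusion-matrix summaries in
percent; 0/0 ratios are reported as 0 — the convention under which an
all-negative predictor on balanced data reads Acc 50, Se 0, Sp 100,
Pre 0, F1 0. Fold dispersion is reported as the standard deviation across
folds (not the standard error). Per-kernel pertinence re-runs the whole
protocol with one kernel enabled at a time and sorts by mean accuracy.

## The synthetic-data generator

The generator exists so that every kernel, and the end-to-end system, is
testable offline with known ground truth. It emulates the *feature
constellation* of piRNAs, not any real genome:

* Background: i.i.d. sequence at GC 0.42 with CpG dinucleotides depleted
  by composition-preserving CG→GC swaps (two passes at rate 0.8). The
  depletion matters: in i.i.d. sequence the observed/expected CpG ratio is
  ~1 and half of all windows would qualify as islands, whereas methylated
  genomes sit near 0.2 — without it the CpG kernel would measure nothing.
* Tracks: telomeres cover the first and last 1 % of each chromosome, a
  centromere the middle 2 %; background histone peaks (10 per Mb per
  mark, 1–3 kb) and background TE annotations (20 per Mb, 200–1000 bp,
  identity drawn low) are scattered uniformly.
* Positives (default 1000) are planted in clusters of 4 within 10 kb
  windows — echoing the K = 4 neighbour default — with 70 % of clusters
  anchored near centromeres/telomeres; each cluster has one strand.
  Sequences are 25–33 nt; the 5' T and 10th A are forced with probability
  0.9 each; 60 % of positive bodies are reverse complements of a random
  transposon-target subsequence (the binding signal; in mammals only a
  minority of piRNAs maps antisense to TEs, but the binding kernel's
  planted effect must be strong enough to be learnable at test scale).
  With probability 0.8 each, a positive receives: an upstream promoter
  motif at 100–1000 bp, an upstream G-quadruplex (the 21 bp telomeric
  motif) at 50–500 bp, an upstream 300 bp CG-rich block at 100–2000 bp, a
  bracketing inverted repeat (60 bp arm upstream, its reverse complement
  downstream, 200–2000 bp away), two flanking high-identity LINE
  annotations within 0.5–5 kb, and overlapping histone peaks per mark.
  Sequence bodies are written into the genome last, so no planting can
  overwrite a piRNA.
* Negatives (default 1000) are unplanted genome slices of the same length
  range, placed uniformly outside cluster windows (± 5 kb), with random
  strand. They emulate the tRNA/miRNA/exon negatives of real protocols
  only in length and in their lack of plantings — no tRNA structure is
  simulated.

Everything is deterministic given `seed`. What passing tests on this
generator show is that each extractor recovers its planted signal and
that the MKL machinery combines and ranks such signals correctly; they do
not show that the planted effect sizes match any real species, where the
same features are weaker, correlated, and partially absent.

A null configuration (all planting rates 0, `cluster_size = 1`,
`centrotelo_fraction = 0`, `plant_sequences = FALSE` so positives are
plain genome slices) serves as the control: every kernel's single-kernel
accuracy should then hover at chance.

### Problem sizes used by the tests and the acceptance script

Unit tests run on 30+30 sequences over a 2 × 0.6 Mb genome; the
end-to-end acceptance checks and `scripts/acceptance.R` use 200+200 over
2 × 2.5 Mb — the generator's reduced evaluation scale, which keeps the
cluster density (≈ 10 % of the genome under cluster windows) comparable
to the 1000+1000 default on 4 × 5 Mb. The null control is generated at
150+150 on the same genome scale; chance-level accuracies are insensitive
to that difference.

## Numerical choices and degenerate inputs

* Distances beyond a window use the window size D as the absence
  sentinel, keeping features bounded and kernel scales stable; positional
  sentinels (cluster, track distances) use the chromosome length.
* Unmapped sequences are legal at prediction time: every
  position-dependent kernel emits its absence sentinel and a warning is
  logged.
* The inverted-repeat extension is greedy and bounded to ±2 kb around
  each seed; overlapping seeds are merged before extension (CG-rich
  repetitive stretches otherwise trigger one extension per seed
  position). Thresholds "longer than 20" and "more than 90 %" are strict.
  Because extension absorbs flanking near-matches while identity stays
  above 0.9, a planted exact arm can be reported a few bases longer than
  planted with identity slightly below 1.
* The duplex engine marks every pairable aligned position at the best
  offset, not only contiguous runs; ties between offsets go to the
  smallest.
* Gaussian kernels are checked symmetric positive semidefinite to an
  eigenvalue floor of −1e−8; `k(x,x) = 1` exactly.
* kernlab's internal class coding can flip the sign of the decision
  function; the wrapper realigns signs against the training labels so
  that positive scores always mean "piRNA".
* Fold assignment, PSO and the generator restore the global RNG state
  where they seed it, so library calls do not perturb user seeds.

## Limitations

* The duplex engine is combinatorial (maximal pairable positions), not
  thermodynamic; no gapped hybridisation, no free-energy model. The
  plug-in structure interface exists precisely so external predictions
  can be substituted.
* Genomic positions are inputs; the package performs no read mapping.
* The A-Myb kernel is only as good as the supplied consensus motifs.
* Kernel matrices are dense N×N; training beyond ~10⁴ sequences per run
  would need low-rank approximations, which are out of scope.
* Per-kernel pertinence on the synthetic data reflects planted effect
  sizes, not biology; on real data it depends on annotation quality
  (ChIP-seq peaks, RepeatMasker ratios) as much as on the feature itself.
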