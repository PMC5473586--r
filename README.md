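# pirmkl — integrative piRNA prediction with multiple kernel learning

PIWI-interacting RNAs (piRNAs) are 25–33 nt small non-coding RNAs of
germline cells that silence transposable elements. They are the largest and
most heterogeneous small-RNA class: they carry no conserved secondary
structure and little sequence conservation, so single-feature classifiers
(k-mer composition, structure, or target binding alone) transfer poorly
across species. What piRNAs do share is a constellation of weak genomic and
epigenomic signals: a 5′ uridine and 10th adenosine (the ping-pong
signature), clustered genomic origin, antisense complementarity to
transposons, and flanking marks — promoter motifs (A-Myb in mouse),
G-quadruplexes, CpG islands, transposable elements, inverted repeats,
repressive histone marks (H3K9me3/H3K27me3) and
pericentromeric/telomeric placement.

`pirmkl` is an R package for classifying candidate small-RNA sequences as
piRNA versus non-piRNA by combining **twelve heterogeneous feature
kernels** in a **multiple kernel learning (MKL) support vector machine**,
for researchers who have candidate sequences, their genomic positions, a
reference genome and annotation tracks — or who want to study which
features carry signal in a given species.

## The model

Each feature extractor maps a sequence *x* to a vector (or a matrix, for
the cluster-context feature); each representation feeds a Gaussian kernel

> k(x, y) = exp(−γ‖x − y‖²)

with the Euclidean norm for vectors and the Frobenius norm for matrices.
The bandwidth γ is selected per kernel: the Jaakkola median heuristic
γ_J = 1/(2·median(D)²) over the pairwise distances D seeds a grid
γ = eⁱ·γ_J, i ∈ {−4,…,4}, and the γ maximising the between-class
inter-cluster distance

> δ(X₊, X₋) = (Σ_{x₊} d(x₊, X̄₋) + Σ_{x₋} d(x₋, X̄₊)) / (l₊ + l₋)

in the kernel-induced space is kept. The twelve kernels K₁…K₁₂ are
combined as K(w) = Σₘ wₘKₘ with w ≥ 0, ‖w‖₂ = 1, and the weights are
optimised jointly with a C-SVM on the precomputed combination by spectral
projected gradient descent (Barzilai–Borwein steps, Armijo acceptance) on
the SVM dual objective — kernels that separate the classes earn large
weights, uninformative ones are shrunk.

The kernels: `U1A10` (ping-pong signature), `KmerFreq` / `KmerPos`
(frequencies and first positions of 32 wildcard k-mers selected from 3,588
candidates, k = 1–5 with ≤ 40 % wildcard positions, by binary particle
swarm optimisation), `TEbinding` (32 triplet structure–sequence elements
of the best antiparallel gapless duplex against a transposon target set),
`Cluster` (pairwise-distance matrix of the K = 4 nearest training
neighbours), `CentroTelo` / `Histone` (distances to annotation tracks),
`AMyb` (upstream promoter motif scan, score 4^L/D), `G4`
(quadparser-style G-quadruplex scan, both strands), `CpG` (sliding-window
CpG-island scan, observed/expected ≥ 0.6), `TEflank` (cumulated identity
and length of flanking transposable elements per class) and `InvRep`
(gapless inverted-repeat alignments > 20 bp, > 90 % identity).

## Worked example

Everything below runs offline: the package ships a seeded synthetic-genome
generator that plants the piRNA feature constellation into a miniature
genome, so the full pipeline is exercised without any downloads.

```r
library(pirmkl)

sim <- plant_dataset(sim_config(n_pos = 200, n_neg = 200,
                                n_chrom = 2, chrom_length = 2.5e6,
                                seed = 1))
cv <- cross_validate(sim$records, sim$genome, k = 5, seed = 1)
print(cv)
```

```
5-fold cross-validation (kernels: U1A10, KmerFreq, KmerPos, TEbinding,
CentroTelo, Histone, Cluster, AMyb, G4, CpG, TEflank, InvRep)

                   Acc           Se          Sp         Pre          F1
fold1            98.75       100.00       97.50       97.56       98.77
fold2           100.00       100.00      100.00      100.00      100.00
fold3           100.00       100.00      100.00      100.00      100.00
fold4           100.00       100.00      100.00      100.00      100.00
fold5           100.00       100.00      100.00      100.00      100.00
mean +- sd 99.75+-0.56 100.00+-0.00 99.50+-1.12 99.51+-1.09 99.75+-0.55
```

The columns are the five usual confusion-matrix summaries in percent
(accuracy, sensitivity, specificity, precision, F1), one row per held-out
fold; every supervised stage (k-mer selection, bandwidths, kernel weights)
is refit inside each fold. Per-kernel pertinence re-runs the
cross-validation with one kernel at a time — the read-out of how much each
biological feature contributes:

```r
per_kernel_pertinence(sim$records, sim$genome, k = 5, seed = 1)
```

```
Per-kernel pertinence (single-kernel CV accuracy, %):
     kernel   Acc    sd
    Histone 99.25 1.118
         G4 98.25 1.118
       AMyb 95.75 2.878
     InvRep 93.50 2.054
        CpG 93.00 3.812
    TEflank 92.50 2.339
      U1A10 90.75 2.092
    Cluster 87.75 3.354
 CentroTelo 84.50 4.809
  TEbinding 75.25 0.559
    KmerPos 62.00 6.287
   KmerFreq 55.50 3.010
```

Here every planted feature scores well above the 50 % chance level, in
proportion to its planted effect size. To train once and predict new
sequences:

```r
fit <- pirna_mkl(sim$records, sim$genome, C = 1, seed = 1)
coef(fit)                                  # learned kernel weights
predict(fit, new_records, sim$genome)      # "positive" / "negative"
```

Real data enter through standard formats: `read_fasta()` for sequences,
genome and transposon targets, `read_bed()` for positions and annotation
tracks, a 9-column TSV for TE annotations (with RepeatMasker-style
mismatch/deletion/substitution ratios). A command-line wrapper
(`inst/cli/pirmkl`) exposes `simulate`, `select-kmers`, `features`,
`train`, `predict`, `evaluate` and `pertinence` subcommands over the same
functions.

## Package layout

* `R/` — domain types and I/O, the twelve feature extractors, the kernel
  engine, the MKL optimiser, the evaluation harness, the synthetic-data
  generator, the CLI.
* `tests/testthat/` — unit and property tests with brute-force oracles,
  plus end-to-end acceptance tests.
* `vignettes/pirmkl-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, limitations.
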