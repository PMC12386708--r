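---
title: "Supervised rank aggregation for SNP feature selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised rank aggregation for SNP feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sraselect)
```

## The problem

Whole-genome sequencing panels routinely carry millions of SNPs for at most
a few thousand individuals. Classifying individuals into populations
(breeds, in the motivating application) from such data is a p >> n problem:
joint model fits are unstable, p-value-based screening breaks down under
massive correlated multiple testing, and most classifiers cannot even hold
the design matrix in memory. `sraselect` implements three feature-selection
strategies of increasing statistical ambition, plus a compact 1D
convolutional classifier to measure what a selected SNP panel is worth:

* **LD tagging** — a purely mechanistic baseline that prunes SNPs in high
  linkage disequilibrium with an already-retained tag;
* **1D-SRA** (one-dimensional supervised rank aggregation) — many
  multinomial logistic regressions on small random SNP subsets, aggregated
  through a mixed linear model and clustered into relevant/irrelevant sets;
* **MD-SRA** (multidimensional supervised rank aggregation) — several
  independent ensemble repeats collapsed into a dense score matrix that is
  clustered directly, skipping the mixed-model solve.

## The ensemble and its aggregation

Both SRA variants start the same way. The P SNP indices are shuffled and
cut into K = floor(P/S) blocks of S SNPs (default S = 250; the incomplete
tail block is kept by default so every SNP gets scored, with a
`drop_remainder` mode for strict floor(P/S) behavior). For each block a
reference-class multinomial logit

  log(P_b / P_B) = alpha_b + beta_b' x,   b = 1..B-1

is fitted to the class labels by damped Newton on the ridge-penalized
likelihood. Each model contributes:

* a **model performance** MP_k: the training cross-entropy
  CE_k = -(1/N) sum_i log p_i,true(i), and
* a **feature performance** FP for each of its S SNPs: the maximum of the
  SNP's class-specific coefficients, taken in absolute value by default
  (`fp_mode = "abs_max"`; see Design choices).

The sparse K x (P+1) performance matrix stores FPs row-wise with CE_k in
the last column; only the O(K*S) non-zeros are kept, in memory and in the
plain-text persistence format.

**1D-SRA** regresses y_k = 1/CE_k on the FP design Z through the mixed
linear model y = mu + Z a + e with a ~ N(0, I var_a), e ~ N(0, I var_e).
The variances are treated as known constants (defaults var_a = 6.5e-5,
var_e = 1.5e-4); only their ratio lambda = var_e/var_a (about 2.31) enters
the solutions. The mixed model equations are solved by preconditioned
conjugate gradients with a Jacobi (diagonal) preconditioner; Z'Z is never
formed, every iteration costs two sparse matrix-vector products, and the
solver stops when the relative residual reaches `tol` (default 1e-10 —
tighter values are accepted but approach float64 attainability). The P
solutions a_hat are clustered by one-dimensional 2-means (10 restarts,
seeded); the cluster whose centroid has the larger absolute value is the
relevant set, a data-driven alternative to an arbitrary effect-size cutoff.

**MD-SRA** repeats the partition-and-fit step W times (default 5) with
independent partitions, collapses each repeat's sparse matrix to a dense
P-vector of FP x (1/CE_k) products, and clusters the resulting P x W score
matrix with 2-means; the relevant cluster is the one whose centroid has
the larger Euclidean norm. No column standardization is applied by default
(the scores already share a scale through the 1/CE weighting); a
`standardize` flag exists for exploration.

## LD tagging

Pairwise LD is the squared Pearson correlation of dosage vectors
(composite LD, so unphased data works; a constant SNP has r² = 0 by
convention and is retained, though QC normally removes it). The scan runs
per chromosome in position order: a SNP is kept as a tag exactly when its
r² with every retained tag within 100 kbp upstream is at most 0.5 (both
defaults configurable). The original full-scale procedure names a 100 kbp region, a
1 kbp moving window and the 0.5 threshold but not the exact pruning
algorithm; the deterministic greedy scan above is order-stable,
inclusion-maximal (every pruned SNP is certified against a retained
in-window tag in the output manifest) and reproduces the intent of keeping
one representative per LD neighborhood. `step_bp` is retained as a
configuration knob for windowed variants.

## The classifier

The evaluation classifier is a 1D CNN over the selected SNP dosage vector:
`n_conv_blocks` repetitions of [convolution (10 kernels, default length
150, capped at the input length) -> ReLU -> batch normalization ->
max-pool(5)], then a flatten and three ReLU dense layers (128/64/32) and a
softmax output. It is trained with Adam (default learning rate 5e-5)
minimizing the focal loss

  FL_i = alpha_b (1 - p_i,b)^2 * CE_i,  alpha_b = N / (B g_b),

which down-weights easy examples and re-balances unequal classes; with the
focusing factor removed and unit weights it reduces to the cross-entropy.
The network is implemented natively in R with matrix operations (im2col
convolutions, exact backpropagation through batch normalization and
max-pooling, Adam with bias correction); gradients are verified against
numerical differentiation in the test suite. The output layer is
zero-initialized so an untrained model predicts exactly uniform class
probabilities — a calibration-friendly start that also stabilizes the
first Adam steps.

Evaluation uses stratified K-fold cross-validation (default 5). Quality is
macro F1 — the harmonic mean of macro-averaged precision and recall, with
zero-count classes contributing zero to the respective average — and the
macro one-vs-rest AUC via the rank-sum formulation with ties credited 0.5.
"Averaging the AUCs" is read as macro averaging of per-class one-vs-rest
AUCs; a per-individual reading has no standard meaning. Per-SNP importance
is the mean over individuals of the class-wise maximum attribution; the
default backend is gradient x input (the aggregation formula is
backend-agnostic, and gradient-based attribution needs no extra
dependency).

## The synthetic-data generator

Real multi-breed sequence panels cannot ship with a package, so every
stage is exercised on simulated data with known ground truth. Class
structure follows the Balding-Nichols model: each SNP has an ancestral
frequency p ~ U(0.1, 0.9), and each class draws its own frequency from
Beta(p(1-F)/F, (1-p)(1-F)/F), whose between-class variance is p(1-p)F. A
planted subset of `n_signal` SNPs uses `fst_signal`; the rest drift at
`fst_background`. F therefore parameterizes effect size directly, which is
exactly the kind of signal (allele-frequency divergence between breeds)
the selection methods target.

LD is induced by finite haplotype pools: per class and per block of
`block_size` SNPs, `haplotypes_per_block` haplotypes are drawn site-wise
Bernoulli(class frequency) and each individual draws two with replacement.
Small pools give strong within-block r² (a pool of 2 forces r² near 1);
large pools approach linkage equilibrium. One subtlety matters for
benchmarking: a finite pool adds roughly 1/(2H) of spurious per-class
drift to *every* SNP, because the pool's realized allele frequency
deviates from the drawn class frequency. The recovery benchmark therefore
uses H = 2N (600), so the realized differentiation matches the nominal
Fst contrast (0.25 planted vs 0.01 background); LD-specific behavior
(tagging, r² limits) is tested separately with small pools. Blocks sit on
one chromosome at 1 SNP per 100 bp with a 10 kbp gap between blocks, so a
block spans well under the 100 kbp tagging window.

What the generator does **not** emulate: recombination-gradient LD decay,
allele-frequency spectra skewed toward rare variants, genotyping error,
relatedness/pedigree structure, and selection sweeps. Passing the
benchmark shows the methods recover frequency-differentiated signal under
clean population structure — not that they are robust to those real-data
complications.

## Benchmarks the package ships

The planted-SNP recovery benchmark (`recovery_benchmark()`): B = 3 classes
of 100, P = 3000 SNPs, 30 planted at Fst 0.25 vs 0.01 background, S = 50,
W = 5, five simulation seeds. Recall is measured against planted SNPs that
survive QC — SNPs the MAF filter removes are unreachable by any selector.
Downstream value is measured by 3-fold cross-validated macro F1 of the
CNN trained on each selected set against a size-matched random SNP subset
(`bench_cnn_config()` scales the kernel and pool to the panel width and
uses 12 epochs at learning rate 2e-3 — problem sizes chosen so the whole
benchmark runs in minutes on one CPU). The classifier sanity check uses
B = 3, 60 planted SNPs at Fst 0.3, trains on the planted panel with 5-fold
cross-validation, and contrasts intact labels against a label permutation,
which must fall to the 1/B chance level.

Two empirical findings from this benchmark are worth recording, because
they deviate from the real-data ordering of the three methods:

* Under these needle-in-haystack conditions 1D-SRA's recall of planted
  SNPs (mean about 0.6 across seeds) sits below MD-SRA's (about 0.8–0.9), and
  MD-SRA's downstream macro F1 is correspondingly higher. Each SNP is
  fitted in exactly one reduced model per partition, so 1D-SRA gives every
  SNP a single noisy observation and the mixed model can only distribute
  one model-level residual across its S member SNPs; MD-SRA's W = 5
  independent repeats give each SNP five looks and average that noise. On
  the real panels both methods operated far from this information limit
  (millions of informative SNPs, permissive relevant clusters), which is
  how the original full-scale comparison favored 1D-SRA.
* Both SRA selections beat size-matched random subsets on every benchmark
  seed, which is the property that makes them feature *selectors* rather
  than feature *samplers*.

## Design choices

* **Ridge default 0.5.** With S of the same order as N (50 vs 300 in the
  benchmark; 250 vs 1460 in the motivating study) an unpenalized
  multinomial fit separates its training data: every cross-entropy
  collapses toward zero and both the 1/CE weights and the coefficient
  magnitudes degrade into separation noise. The default matches the
  unit-strength L2 regularization of standard multinomial solvers; a
  near-zero ridge (1e-6) remains available to study the unpenalized limit,
  and the ridge follows the weight-decay convention (intercepts included)
  so independent oracle fits use the identical penalty.
* **FP default abs-max.** The maximum of signed class coefficients
  discards SNPs whose discriminative effect is negative for every
  non-reference class — roughly 1/B of planted SNPs — and halves benchmark
  recall; the absolute maximum keeps them. `signed_max` is available for
  strict parity with the original formula, whose sign convention is not
  stated.
* **Reference class** is the last label in lexicographic order, fixed and
  logged by the fit.
* **Jacobi preconditioner.** "Block diagonal elements of the coefficient
  matrix" leaves the blocks undefined; the intercept/SNP split gives a
  natural 1 + P diagonal, which is well-defined, cheap and reproducible.
* **Known variances.** var_a and var_e are never estimated (the motivating
  analysis fixed them because REML at that scale is infeasible); tests
  verify solutions depend on them only through lambda.
* **K-means ties** (equal centroid magnitude/norm): the smaller cluster is
  taken as relevant, on the grounds that relevant SNPs are expected to be
  the minority.
* **Degenerate inputs.** Cross-entropies at or below 1e-12 abort
  aggregation ("degenerate model fit"); probabilities are clamped at 1e-15
  before logs; SNPs never scored under remainder-dropping get a_hat = 0
  and are forced into the irrelevant set with a warning; a constant a_hat
  vector is a "no separation" error rather than an arbitrary split.
* **Persistence formats** are plain text: VCF 4.2 + a two-column labels
  TSV for genotypes, a row-wise text format for the performance matrix
  (preserving O(K*S) storage), JSON for truth sets, manifests and metrics.
* **QC conventions.** Call-rate and MAF removal are strict inequalities
  (a SNP at exactly 5% MAF stays); MAF uses non-missing dosages only;
  multiallelic records are dropped at parse time (ALT containing a comma);
  residual missing genotypes after the call-rate filter are imputed to the
  per-SNP mode, with a strict mode that errors instead. Filters are
  computed on whatever dataset is passed in, so upstream subsetting policy
  is the caller's decision.

## Known limitations

* The native CNN is CPU-bound R; it is sized for panels up to a few
  thousand SNPs, not for hundreds of thousands.
* Training cross-entropy (not cross-validated loss) scores the reduced
  models, faithfully to the original procedure; with heavily
  overparameterized blocks this rewards fit, not generalization — the
  ridge default mitigates but does not remove this.
* At benchmark scale the mixed-model solve is milliseconds, so the large
  wall-clock advantage MD-SRA shows over 1D-SRA on full-size panels (where
  the aggregation solve and its storage dominate) cannot be observed here.
* The 2-means relevant/irrelevant split inherits k-means' sensitivity to
  heavy tails: a handful of extreme solutions can shrink the relevant
  cluster drastically on unlucky partitions.
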