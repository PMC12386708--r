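# sraselect

Feature selection for ultra-high-dimensional SNP genotype panels, ahead of
multi-class classification (for example, assigning individuals to breeds
from whole-genome sequence). With millions of SNPs and only hundreds to
thousands of individuals (p >> n), joint models are unstable and
p-value-based screening breaks down under correlated multiple testing;
`sraselect` implements three selection strategies that sidestep both, plus
a compact 1D convolutional classifier to measure what a selected panel is
worth.

## Methods

**LD tagging** — the mechanistic baseline. Pairwise linkage disequilibrium
is the squared dosage correlation R²; scanning each chromosome in position
order, a SNP is kept as a tag iff its R² with every retained tag within
100 kbp is ≤ 0.5.

**1D-SRA** (one-dimensional supervised rank aggregation). The P SNPs are
shuffled into K = floor(P/S) blocks of S; each block gets a ridge-penalized
multinomial logit `log(P_b/P_B) = α_b + β_b'x` whose fit is summarized by
the training cross-entropy `CE_k = -(1/N) Σ_i log p_i,true(i)` and whose
SNP coefficients yield per-SNP feature performances FP (max |β̂| by
default). The aggregation step fits the mixed linear model

    y = μ + Z a + ε,   y_k = 1/CE_k,   a ~ N(0, I σ²_a),  ε ~ N(0, I σ²_ε)

with Z the sparse K×P matrix of FPs and fixed variances (defaults 6.5e-5 /
1.5e-4, so λ = σ²_ε/σ²_a ≈ 2.31), solved by preconditioned conjugate
gradients with a Jacobi preconditioner (Z'Z never materialized). The SNP
solutions â are split into relevant/irrelevant by one-dimensional 2-means;
the cluster with the larger |centroid| is relevant.

**MD-SRA** (multidimensional supervised rank aggregation). W = 5
independent ensemble repeats are collapsed into a dense P×W score matrix
(each SNP's FP times 1/CE of its model); 2-means on the rows picks the
cluster whose centroid has the larger L2 norm. This skips the mixed-model
solve — the expensive step at full panel scale — while keeping the
supervised weighting.

**Classifier** — a native 1D CNN (conv → ReLU → batch-norm → max-pool,
then three dense layers and softmax) trained with Adam on the focal loss
`FL_i = α_b (1-p_ib)² CE_i` with `α_b = N/(B g_b)`, evaluated by
stratified cross-validation with macro F1 and macro one-vs-rest AUC, and
per-SNP attributions aggregated as the mean over individuals of the
class-wise maximum.

A Balding–Nichols simulator (`simulate_dataset()`) generates
breed-structured panels with haplotype-block LD and planted
class-discriminative SNPs, so the whole pipeline is testable without
external data.

## Worked example

```r
library(sraselect)

sim <- simulate_dataset(sim_config(n_per_class = c(60, 60, 60), p_snps = 1000,
                                   n_signal = 20, fst_signal = 0.3,
                                   haplotypes_per_block = 360, seed = 42))
ds <- apply_qc(sim$dataset)
ds
#> genotype_dataset: 180 individuals x 999 SNPs
#>   chromosomes: 1
#>   classes: class1=60, class2=60, class3=60

sel <- select_md_sra(ds, w_repeats = 5, s = 50, seed = 7)
sel
#> feature_selection_result [md_sra]: 10 of 999 SNPs relevant (reduction 99.00%)
sum(sim$truth$signal_snp_ids %in% sel$relevant_ids)
#> [1] 10     # every selected SNP is a planted discriminative SNP

ds_sel <- subset_dataset(ds, snps = sel$relevant_ids)
report <- train_cv(ds_sel, bench_cnn_config(n_snps(ds_sel), seed = 1),
                   n_folds = 3)
report
#> metrics_report: validation macro F1 = 97.82% (sd 0.96), macro AUC = 0.9989 (sd 0.0012)
```

The selection reduced 999 QC-passing SNPs to 10 — all of them planted
signal SNPs — and a classifier trained on that panel separates the three
simulated populations almost perfectly (macro F1 97.8%, AUC 0.999).

`read_vcf()` / `write_vcf()` move the same objects in and out of VCF 4.x
with a two-column sample/class TSV; `run_pipeline()` chains
simulate/load → QC → split → select → train → attribute from a single JSON
config and writes a reproducibility manifest; `inst/cli/sra-select.R` is a
thin command-line front end with matching subcommands.

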