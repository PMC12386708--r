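#' CNN configuration scaled to a given input width
#'
#' Benchmark-sized variant of [cnn_config()]: one convolution block with ten
#' kernels, kernel length capped at `min(10, input_len)` and pool window
#' shrunk so any selected panel down to a handful of SNPs still builds, with
#' a training budget (12 epochs, batch 32, Adam at 2e-3) sized for panels of
#' a few hundred to a few thousand SNPs.
#'
#' @param input_len Number of SNPs the classifier will see.
#' @param seed Seed for initialization and shuffling.
#' @param epochs,learning_rate Overridable training budget.
#' @return A [cnn_config()].
#' @export
bench_cnn_config <- function(input_len, seed, epochs = 12,
                             learning_rate = 2e-3) {
  k <- min(10L, input_len)
  pool <- max(1L, min(5L, input_len - k + 1L))
  cnn_config(n_conv_blocks = 1, kernels_per_conv = 10, kernel_size = k,
             pool_size = pool, dense_sizes = c(128, 64, 32),
             learning_rate = learning_rate, epochs = epochs,
             batch_size = 32, seed = seed)
}

#' Simulation settings of the planted-SNP recovery benchmark
#'
#' Three classes of 100 individuals, 3000 SNPs, 30 planted discriminative
#' SNPs at Fst 0.25 against an 0.01 background. The haplotype pool is set to
#' 2N so the realized class differentiation matches the nominal
#' Balding-Nichols parameters (small pools add ~1/(2H) of spurious drift to
#' every SNP).
#'
#' @param seed Simulation seed.
#' @return A [sim_config()].
#' @export
bench_sim_config <- function(seed) {
  sim_config(n_per_class = c(100, 100, 100), p_snps = 3000,
             fst_background = 0.01, fst_signal = 0.25, n_signal = 30,
             block_size = 10, haplotypes_per_block = 600, seed = seed)
}

#' Planted-SNP recovery benchmark
#'
#' For each seed: simulate the benchmark dataset, apply QC, run 1D-SRA and
#' MD-SRA (S = 50 SNPs per reduced model, W = 5 repeats), measure the recall
#' of planted SNPs that survive QC in each relevant cluster, and (optionally)
#' compare downstream cross-validated macro F1 of classifiers trained on
#' each selected set against size-matched random SNP subsets.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param s SNPs per reduced model (default 50).
#' @param w_repeats MD-SRA repeats (default 5).
#' @param classify Also train classifiers for the downstream comparison?
#' @param n_folds Cross-validation folds for the downstream comparison.
#' @param tagging Also run LD tagging and its downstream classifier?
#' @return Data frame with one row per seed: recalls, selected-set sizes and
#'   (when `classify`) validation macro F1 for 1D-SRA, MD-SRA and the two
#'   random baselines (and tagging when requested).
#' @export
recovery_benchmark <- function(seeds, s = 50, w_repeats = 5,
                               classify = TRUE, n_folds = 3,
                               tagging = FALSE) {
  rows <- lapply(seeds, function(seed) {
    sim <- simulate_dataset(bench_sim_config(seed))
    ds <- apply_qc(sim$dataset)
    surv <- intersect(sim$truth$signal_snp_ids, ds$snp_ids)
    s1 <- select_1d_sra(ds, s = s, seed = derive_seed(seed, 21L))
    sm <- select_md_sra(ds, w_repeats = w_repeats, s = s,
                        seed = derive_seed(seed, 22L))
    out <- data.frame(
      seed = seed,
      n_signal_surviving = length(surv),
      recall_1d = mean(surv %in% s1$relevant_ids),
      recall_md = mean(surv %in% sm$relevant_ids),
      n_1d = length(s1$relevant_ids),
      n_md = length(sm$relevant_ids))
    if (classify) {
      set.seed(derive_seed(seed, 23L))
      rnd1 <- ds$snp_ids[sort(sample.int(n_snps(ds), out$n_1d))]
      rndm <- ds$snp_ids[sort(sample.int(n_snps(ds), out$n_md))]
      cv_f1 <- function(ids, cseed) {
        dsel <- subset_dataset(ds, snps = ids)
        train_cv(dsel, bench_cnn_config(length(ids), cseed),
                 n_folds = n_folds)$macro_f1
      }
      out$f1_1d <- cv_f1(s1$relevant_ids, derive_seed(seed, 31L))
      out$f1_md <- cv_f1(sm$relevant_ids, derive_seed(seed, 32L))
      out$f1_random_1d <- cv_f1(rnd1, derive_seed(seed, 33L))
      out$f1_random_md <- cv_f1(rndm, derive_seed(seed, 34L))
      if (tagging) {
        tg <- select_tag_snps(ds)
        out$n_tag <- length(tg$relevant_ids)
        out$recall_tag <- mean(surv %in% tg$relevant_ids)
        out$f1_tag <- cv_f1(tg$relevant_ids, derive_seed(seed, 35L))
      }
    }
    out
  })
  do.call(rbind, rows)
}
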