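#' Simulation configuration for breed-structured genotype panels
#'
#' Emulates a multi-population SNP panel in which classes (breeds) differ by
#' allele-frequency drift. Per-SNP class frequencies follow the
#' Balding-Nichols model: given an ancestral frequency p and differentiation
#' F (an Fst analogue), each class draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so the between-class variance is p(1-p)F.
#' A subset of `n_signal` planted SNPs uses the larger `fst_signal`, making
#' them class-discriminative; everything else drifts at `fst_background`.
#' Linkage disequilibrium is induced by drawing each individual's two
#' haplotypes per block from a finite per-class haplotype pool.
#'
#' @param n_per_class Integer vector of class sizes (length B >= 2).
#' @param p_snps Total number of SNPs.
#' @param fst_background Differentiation of background SNPs, in (0, 1).
#' @param fst_signal Differentiation of planted SNPs (>= `fst_background`).
#' @param n_signal Number of planted discriminative SNPs.
#' @param block_size SNPs per LD block.
#' @param haplotypes_per_block Haplotype pool size per class and block;
#'   smaller pools give stronger within-block LD.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_class = c(100, 100, 100), p_snps = 3000,
                       fst_background = 0.01, fst_signal = 0.25,
                       n_signal = 30, block_size = 10,
                       haplotypes_per_block = 8, seed = 1) {
  stopifnot(length(n_per_class) >= 2, all(n_per_class >= 1), p_snps >= 1,
            n_signal <= p_snps, n_signal >= 0, block_size >= 1,
            haplotypes_per_block >= 1)
  if (fst_background <= 0 || fst_background >= 1 ||
      fst_signal <= 0 || fst_signal >= 1) {
    stop("fst parameters must lie in (0, 1)")
  }
  if (fst_signal < fst_background) stop("fst_signal must be >= fst_background")
  structure(list(n_per_class = as.integer(n_per_class),
                 p_snps = as.integer(p_snps),
                 fst_background = fst_background, fst_signal = fst_signal,
                 n_signal = as.integer(n_signal),
                 block_size = as.integer(block_size),
                 haplotypes_per_block = as.integer(haplotypes_per_block),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-class allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are uniform on [0.1, 0.9]; each class then draws its
#' own frequency from the Balding-Nichols Beta distribution with the SNP's
#' differentiation parameter. Planted signal SNPs are chosen uniformly at
#' random among SNP indices.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` list: `signal_snp_idx` (planted SNP indices),
#'   `signal_snp_ids`, `class_freqs` (B x P matrix), `ancestral` (P vector).
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  b <- length(cfg$n_per_class)
  p <- cfg$p_snps
  ancestral <- stats::runif(p, 0.1, 0.9)
  fst <- rep(cfg$fst_background, p)
  signal_idx <- sort(sample.int(p, cfg$n_signal))
  fst[signal_idx] <- cfg$fst_signal
  shape1 <- ancestral * (1 - fst) / fst
  shape2 <- (1 - ancestral) * (1 - fst) / fst
  class_freqs <- matrix(0, nrow = b, ncol = p)
  for (k in seq_len(b)) {
    class_freqs[k, ] <- stats::rbeta(p, shape1, shape2)
  }
  structure(list(signal_snp_idx = signal_idx,
                 signal_snp_ids = sprintf("snp%06d", signal_idx),
                 class_freqs = class_freqs, ancestral = ancestral),
            class = "sim_truth")
}

#' Simulate genotypes with haplotype-block linkage disequilibrium
#'
#' For every class and LD block, a pool of `haplotypes_per_block` haplotypes
#' is drawn site-wise Bernoulli(class frequency); each individual then draws
#' two pool haplotypes with replacement per block and its dosage is their
#' sum. SNPs sit on one chromosome at 1 SNP per 100 bp within a block with a
#' 10 kbp gap between blocks, so each block spans well under 100 kbp.
#'
#' @param truth A `sim_truth` from [simulate_frequencies()].
#' @param cfg The same [sim_config()].
#' @return List with `dataset` (a labeled [genotype_dataset()]) and `truth`
#'   (the input truth, with `signal_snp_ids` aligned to the dataset).
#' @export
simulate_genotypes <- function(truth, cfg) {
  set.seed(cfg$seed + 1L)
  b <- length(cfg$n_per_class)
  p <- cfg$p_snps
  n <- sum(cfg$n_per_class)
  starts <- seq(1L, p, by = cfg$block_size)
  dos <- matrix(0L, nrow = n, ncol = p)
  row_off <- c(0L, cumsum(cfg$n_per_class))
  for (bl in seq_along(starts)) {
    cols <- starts[bl]:min(starts[bl] + cfg$block_size - 1L, p)
    s <- length(cols)
    for (k in seq_len(b)) {
      freq <- truth$class_freqs[k, cols]
      pool <- matrix(stats::rbinom(cfg$haplotypes_per_block * s, 1L,
                                   rep(freq, each = cfg$haplotypes_per_block)),
                     nrow = cfg$haplotypes_per_block, ncol = s)
      nk <- cfg$n_per_class[k]
      h1 <- sample.int(cfg$haplotypes_per_block, nk, replace = TRUE)
      h2 <- sample.int(cfg$haplotypes_per_block, nk, replace = TRUE)
      dos[(row_off[k] + 1L):row_off[k + 1L], cols] <-
        pool[h1, , drop = FALSE] + pool[h2, , drop = FALSE]
    }
  }
  block_of <- (seq_len(p) - 1L) %/% cfg$block_size
  within <- (seq_len(p) - 1L) %% cfg$block_size
  pos <- 1L + block_of * 10000L + within * 100L
  labels <- rep(sprintf("class%d", seq_len(b)), cfg$n_per_class)
  ds <- genotype_dataset(
    dosages = dos, snp_ids = sprintf("snp%06d", seq_len(p)),
    chrom = rep("1", p), pos = pos,
    sample_ids = sprintf("ind%05d", seq_len(n)), labels = labels)
  list(dataset = ds, truth = truth)
}

#' Simulate a complete labeled genotype dataset
#'
#' Convenience wrapper chaining [simulate_frequencies()] and
#' [simulate_genotypes()].
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` and `truth` as in [simulate_genotypes()].
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  truth <- simulate_frequencies(cfg)
  simulate_genotypes(truth, cfg)
}

#' Write a simulated dataset to VCF + labels TSV + truth JSON
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, "genotypes.vcf")
  labels <- file.path(dir, "labels.tsv")
  truth <- file.path(dir, "truth.json")
  write_vcf(sim$dataset, vcf, labels_path = labels)
  jsonlite::write_json(list(signal_snp_ids = sim$truth$signal_snp_ids),
                       truth, auto_unbox = FALSE)
  invisible(c(vcf = vcf, labels = labels, truth = truth))
}
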