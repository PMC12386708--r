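# Small in-code fixtures shared across test files.

# A hand-built dataset: n individuals, dosage matrix given column-wise.
toy_dataset <- function(dosage_cols, labels = NULL, chrom = NULL, pos = NULL,
                        multiallelic = NULL) {
  dos <- do.call(cbind, dosage_cols)
  p <- ncol(dos)
  genotype_dataset(
    dosages = dos,
    snp_ids = sprintf("s%02d", seq_len(p)),
    chrom = chrom %||% rep("1", p),
    pos = pos %||% seq_len(p) * 100L,
    sample_ids = sprintf("i%02d", seq_len(nrow(dos))),
    labels = labels,
    multiallelic = multiallelic)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force 2-means: minimum within-cluster sum of squares over all
# 2-partitions of the rows (independent oracle for small inputs).
brute_two_means <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  best <- NULL
  best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(grp)) < 2) next
    ss <- 0
    for (g in 1:2) {
      rows <- m[grp == g, , drop = FALSE]
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr)^2)
    }
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- grp
    }
  }
  list(cluster = best, ss = best_ss)
}

# Within-cluster SS of a given assignment.
partition_ss <- function(m, cluster) {
  m <- as.matrix(m)
  ss <- 0
  for (g in unique(cluster)) {
    rows <- m[cluster == g, , drop = FALSE]
    ss <- ss + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  ss
}

# The recovery benchmark is shared by several acceptance checks; compute it
# once per test run.
bench_cache <- new.env(parent = emptyenv())
get_benchmark <- function() {
  if (is.null(bench_cache$result)) {
    bench_cache$result <- recovery_benchmark(seeds = 1:5, classify = TRUE)
  }
  bench_cache$result
}
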