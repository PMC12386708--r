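#' Build the weighted dense score matrix for multidimensional aggregation
#'
#' Runs `w_repeats` independent ensemble repeats (fresh random partition +
#' block fits each time) and collapses each repeat's sparse performance
#' matrix into one dense P-vector: every SNP's feature performance from its
#' unique reduced model, multiplied by the reciprocal of that model's
#' cross-entropy, so SNPs from better-fitting models carry more weight.
#' SNPs left unscored by a repeat (remainder-dropping mode) keep a zero in
#' that column.
#'
#' @param ds A labeled, QC'd [genotype_dataset()].
#' @param w_repeats Number of repeats W (default 5).
#' @param s SNPs per reduced model (default 250).
#' @param master_seed Master seed; repeat seeds are derived from it.
#' @param drop_remainder Discard incomplete tail blocks?
#' @param ridge Ridge weight for the block fits.
#' @param fp_mode Feature-performance mode, `"abs_max"` (default) or
#'   `"signed_max"`.
#' @return A `dense_score_matrix`: `v` (P x W matrix, rownames = SNP ids),
#'   `repeat_seeds`, `ce_loss` (list of per-repeat K-vectors).
#' @export
build_score_matrix <- function(ds, w_repeats = 5, s = 250, master_seed = 1,
                               drop_remainder = FALSE, ridge = 0.5,
                               fp_mode = "abs_max") {
  stopifnot(w_repeats >= 1)
  p <- n_snps(ds)
  v <- matrix(0, nrow = p, ncol = w_repeats,
              dimnames = list(ds$snp_ids, NULL))
  repeat_seeds <- integer(w_repeats)
  ce_list <- vector("list", w_repeats)
  for (w in seq_len(w_repeats)) {
    repeat_seeds[w] <- derive_seed(master_seed, w)
    part <- partition_features(p, s, seed = repeat_seeds[w],
                               drop_remainder = drop_remainder)
    fits <- tryCatch(
      fit_all_blocks(ds, part, ridge = ridge, fp_mode = fp_mode),
      error = function(e) stop(sprintf("repeat %d: %s", w, conditionMessage(e))))
    pm <- build_performance_matrix(fits, part)
    for (k in seq_along(pm$ce_loss)) {
      v[pm$row_snp_indices[[k]], w] <-
        pm$row_fp_values[[k]] / pm$ce_loss[k]
    }
    ce_list[[w]] <- pm$ce_loss
  }
  structure(list(v = v, repeat_seeds = repeat_seeds, ce_loss = ce_list),
            class = "dense_score_matrix")
}

#' Select relevant SNPs by multidimensional 2-means
#'
#' Clusters the P rows of the W-dimensional score matrix into two groups
#' (k-means, 10 restarts, seeded). The cluster whose centroid has the larger
#' Euclidean (L2) norm in W-dimensional space is the relevant set; on a tie
#' the smaller cluster is taken. With W = 1 this degenerates to the
#' one-dimensional rule (absolute value = L2 norm).
#'
#' @param v A [build_score_matrix()] result (or bare P x W matrix).
#' @param seed Integer seed for the k-means restarts.
#' @param standardize Standardize columns to unit variance before
#'   clustering? Off by default: the scores are already weighted and share a
#'   common scale across repeats.
#' @return A [feature_selection_result()] with method `"md_sra"`.
#' @export
select_relevant_md <- function(v, seed, standardize = FALSE) {
  m <- if (inherits(v, "dense_score_matrix")) v$v else as.matrix(v)
  if (any(!is.finite(m))) stop("non-finite scores")
  snp_ids <- rownames(m)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(nrow(m)))
  mc <- m
  if (standardize) {
    sds <- apply(mc, 2, stats::sd)
    sds[sds == 0] <- 1
    mc <- sweep(mc, 2, sds, "/")
  }
  km <- two_means(mc, seed)
  norms <- sqrt(rowSums(km$centers^2))
  relevant_cluster <- if (norms[1] == norms[2]) {
    which.min(km$size)
  } else {
    which.max(norms)
  }
  assign <- factor(ifelse(km$cluster == relevant_cluster,
                          "relevant", "irrelevant"),
                   levels = c("relevant", "irrelevant"))
  names(assign) <- snp_ids
  zero_rows <- sum(rowSums(m != 0) == 0)
  feature_selection_result(
    relevant_ids = snp_ids[assign == "relevant"],
    cluster_assignments = assign,
    centroids = km$centers, method = "md_sra",
    diagnostics = list(centroid_norms = norms, cluster_sizes = km$size,
                       n_zero_rows = zero_rows))
}

#' Multidimensional supervised rank aggregation, end to end
#'
#' @param ds A labeled, QC'd [genotype_dataset()].
#' @param w_repeats Number of ensemble repeats W (default 5).
#' @param s SNPs per reduced model (default 250).
#' @param seed Master seed.
#' @param drop_remainder,ridge,fp_mode Passed to [build_score_matrix()].
#' @param standardize Passed to [select_relevant_md()].
#' @return A [feature_selection_result()] with method `"md_sra"`.
#' @export
select_md_sra <- function(ds, w_repeats = 5, s = 250, seed = 1,
                          drop_remainder = FALSE, ridge = 0.5,
                          standardize = FALSE, fp_mode = "abs_max") {
  v <- build_score_matrix(ds, w_repeats = w_repeats, s = s,
                          master_seed = seed,
                          drop_remainder = drop_remainder, ridge = ridge,
                          fp_mode = fp_mode)
  res <- select_relevant_md(v, seed = derive_seed(seed, 0L),
                            standardize = standardize)
  res$diagnostics$repeat_seeds <- v$repeat_seeds
  res
}
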