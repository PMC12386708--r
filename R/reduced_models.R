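#' Derive a reproducible child seed from a master seed
#'
#' Deterministic mixing keeps every child inside the 32-bit integer range so
#' it can be handed to `set.seed()`.
#'
#' @param master Integer master seed.
#' @param index Integer stream index (>= 0).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, index) {
  x <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(index) * 8191 + 1
  as.integer(x %% 2147483647L) + 1L
}

#' Randomly partition SNP indices into reduced-model blocks
#'
#' Shuffles the indices `1..p_total` and cuts the permutation into
#' consecutive blocks of `s` SNPs. With `drop_remainder = TRUE` the
#' incomplete tail is discarded, giving exactly `floor(p_total / s)` blocks
#' (so a panel of 11,915,233 SNPs at S = 250 yields K = 47,660 reduced
#' models); otherwise the tail forms a final smaller block and every SNP is
#' scored.
#'
#' @param p_total Total number of SNPs.
#' @param s Block size (number of SNPs per reduced model).
#' @param seed Integer seed for the shuffle.
#' @param drop_remainder Discard the incomplete tail block?
#' @return A `block_partition`: list with `blocks` (list of integer vectors),
#'   `p_total`, `s`, `seed`.
#' @export
partition_features <- function(p_total, s, seed, drop_remainder = FALSE) {
  if (s < 1 || s > p_total) stop("block size s must satisfy 1 <= s <= p_total")
  set.seed(seed)
  perm <- sample.int(p_total)
  k_full <- p_total %/% s
  ends <- seq_len(k_full) * s
  blocks <- lapply(seq_len(k_full), function(k) perm[(ends[k] - s + 1):ends[k]])
  if (!drop_remainder && p_total %% s > 0) {
    blocks[[k_full + 1L]] <- perm[(k_full * s + 1L):p_total]
  }
  structure(list(blocks = blocks, p_total = as.integer(p_total),
                 s = as.integer(s), seed = as.integer(seed)),
            class = "block_partition")
}

#' Cross-entropy loss of class probabilities
#'
#' Mean negative log-probability assigned to the true class,
#' `-(1/N) * sum_i log p[i, true_i]`. Probabilities are clamped at 1e-15
#' before the log.
#'
#' @param true_labels Factor or character vector of N true classes.
#' @param probs N x B matrix of class probabilities; columns must be named by
#'   class (or ordered as `levels(true_labels)`), rows summing to 1 within
#'   1e-8.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(true_labels, probs) {
  if (!is.factor(true_labels)) true_labels <- factor(true_labels)
  if (nrow(probs) != length(true_labels)) stop("shape mismatch")
  if (!is.null(colnames(probs))) {
    if (!all(levels(true_labels) %in% colnames(probs))) {
      stop("probability columns do not cover all classes")
    }
    col <- match(as.character(true_labels), colnames(probs))
  } else {
    if (ncol(probs) < nlevels(true_labels)) stop("shape mismatch")
    col <- as.integer(true_labels)
  }
  if (any(abs(rowSums(probs) - 1) > 1e-8)) {
    stop("probability rows must sum to 1")
  }
  p_true <- pmax(probs[cbind(seq_along(col), col)], 1e-15)
  -mean(log(p_true))
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1L, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Fit a penalized multinomial logistic regression on one SNP block
#'
#' Reference-class multinomial logit `log(P_b / P_B) = alpha_b + beta_b' x`
#' fitted by damped Newton on the penalized negative log-likelihood
#' `NLL + ridge * ||theta||^2` (weight-decay convention as in `nnet`,
#' penalizing intercepts too). The reference class is the last label in
#' lexicographic order. Model fit is summarized by the unpenalized training
#' cross-entropy, and each SNP's feature performance is the absolute
#' maximum (default) or signed maximum of its class-specific coefficients.
#'
#' With `s` of the same order as the number of individuals, an unpenalized
#' fit separates the training classes and every model's cross-entropy
#' collapses toward zero, destroying the performance weighting downstream;
#' the default `ridge = 0.5` (the classic unit-strength L2 of regularized
#' multinomial solvers) keeps coefficients and cross-entropies informative.
#' Near-zero ridge remains available for studying the unpenalized limit.
#'
#' @param ds A labeled [genotype_dataset()].
#' @param block Integer vector of SNP column indices.
#' @param ridge Nonnegative ridge weight (default 0.5).
#' @param fp_mode `"abs_max"` (default; negative class effects count) or
#'   `"signed_max"` (plain maximum across class rows).
#' @param max_iter Maximum Newton iterations.
#' @param grad_tol Convergence threshold on the max-abs gradient.
#' @return A `reduced_model_fit`: `alpha_hat` ((B-1)-vector), `beta_hat`
#'   ((B-1) x S matrix), `ce_loss`, `feature_performance` (S-vector),
#'   `block`, `probs` (N x B), `classes`, `iterations`.
#' @export
fit_block_model <- function(ds, block, ridge = 0.5,
                            fp_mode = c("abs_max", "signed_max"),
                            max_iter = 200L, grad_tol = 1e-8) {
  fp_mode <- match.arg(fp_mode)
  if (is.null(ds$labels)) stop("labels required to fit a block model")
  y <- ds$labels
  if (nlevels(y) < 2) stop("labels cover a single class")
  classes <- levels(y)           # reference = last lexicographic level
  b_total <- length(classes)
  x <- ds$dosages[, block, drop = FALSE]
  storage.mode(x) <- "double"
  n <- nrow(x)
  s <- ncol(x)
  xd <- cbind(intercept = 1, x)
  q <- ncol(xd)                  # s + 1 columns
  nb <- b_total - 1L
  y_ind <- matrix(0, n, nb)
  for (b in seq_len(nb)) y_ind[, b] <- as.numeric(y == classes[b])

  obj <- function(theta) {
    th <- matrix(theta, q, nb)
    eta <- cbind(xd %*% th, 0)
    m <- apply(eta, 1L, max)
    lse <- m + log(rowSums(exp(eta - m)))
    ll <- sum(rowSums(y_ind * eta[, seq_len(nb), drop = FALSE])) -
      sum(lse)   # reference class contributes eta = 0
    -ll + ridge * sum(theta^2)
  }
  grad_probs <- function(theta) {
    th <- matrix(theta, q, nb)
    eta <- cbind(xd %*% th, 0)
    p <- softmax_rows(eta)
    g <- crossprod(xd, p[, seq_len(nb), drop = FALSE] - y_ind)
    list(grad = as.vector(g) + 2 * ridge * theta, probs = p)
  }

  theta <- numeric(q * nb)
  iter <- 0L
  repeat {
    gp <- grad_probs(theta)
    gnorm <- max(abs(gp$grad))
    if (gnorm <= grad_tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "block model did not converge (block starting at SNP %d, grad %.3g)",
        block[1], gnorm))
    }
    p <- gp$probs
    # Hessian: (B-1)q x (B-1)q blocks X' diag(p_b (I{b==b'} - p_b')) X
    h <- matrix(0, q * nb, q * nb)
    for (b1 in seq_len(nb)) {
      for (b2 in b1:nb) {
        w <- if (b1 == b2) p[, b1] * (1 - p[, b1]) else -p[, b1] * p[, b2]
        blk <- crossprod(xd * w, xd)
        r1 <- (b1 - 1L) * q + seq_len(q)
        r2 <- (b2 - 1L) * q + seq_len(q)
        h[r1, r2] <- blk
        if (b1 != b2) h[r2, r1] <- blk
      }
    }
    diag(h) <- diag(h) + 2 * ridge
    step <- tryCatch(solve(h, gp$grad),
                     error = function(e) gp$grad / max(diag(h)))
    f0 <- obj(theta)
    lam <- 1
    repeat {
      theta_new <- theta - lam * step
      if (obj(theta_new) <= f0 + 1e-12 * abs(f0) || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- theta_new
    iter <- iter + 1L
  }

  th <- matrix(theta, q, nb)
  probs <- softmax_rows(cbind(xd %*% th, 0))
  colnames(probs) <- classes
  ce <- cross_entropy(y, probs)
  beta_hat <- t(th[-1L, , drop = FALSE])   # (B-1) x S
  alpha_hat <- th[1L, ]
  fp <- if (fp_mode == "signed_max") {
    apply(beta_hat, 2L, max)
  } else {
    apply(abs(beta_hat), 2L, max)
  }
  structure(list(block = as.integer(block), alpha_hat = alpha_hat,
                 beta_hat = beta_hat, ce_loss = ce,
                 feature_performance = as.numeric(fp), probs = probs,
                 classes = classes, iterations = iter),
            class = "reduced_model_fit")
}

#' Fit every block of a partition
#'
#' @param ds A labeled [genotype_dataset()].
#' @param partition A [partition_features()] result.
#' @param ridge,fp_mode Passed to [fit_block_model()].
#' @return List of `reduced_model_fit`, one per block.
#' @export
fit_all_blocks <- function(ds, partition, ridge = 0.5,
                           fp_mode = "abs_max") {
  lapply(seq_along(partition$blocks), function(k) {
    fit_block_model(ds, partition$blocks[[k]], ridge = ridge,
                    fp_mode = fp_mode)
  })
}

#' Assemble the sparse model performance matrix
#'
#' Conceptually a K x (P + 1) matrix whose row k carries the feature
#' performances of the S SNPs fitted in reduced model k (all other SNPs
#' implicitly zero) and that model's cross-entropy in the last column. Only
#' the O(K * S) non-zero structure is stored.
#'
#' @param fits List of [fit_block_model()] results, one per block.
#' @param partition The [partition_features()] result that produced them.
#' @return A `performance_matrix`: `row_snp_indices`, `row_fp_values` (lists
#'   of length K), `ce_loss` (K-vector), `p_total`.
#' @export
build_performance_matrix <- function(fits, partition) {
  if (length(fits) != length(partition$blocks)) {
    stop("one fit per block required")
  }
  idx <- lapply(fits, function(f) f$block)
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx)) stop("duplicate block index across rows")
  structure(list(row_snp_indices = idx,
                 row_fp_values = lapply(fits, `[[`, "feature_performance"),
                 ce_loss = vapply(fits, `[[`, numeric(1), "ce_loss"),
                 p_total = partition$p_total),
            class = "performance_matrix")
}

#' @export
print.performance_matrix <- function(x, ...) {
  k <- length(x$ce_loss)
  nnz <- sum(lengths(x$row_snp_indices))
  cat(sprintf("performance_matrix: K = %d reduced models, P = %d SNPs, %d stored FP entries\n",
              k, x$p_total, nnz))
  cat(sprintf("  cross-entropy range: [%.4g, %.4g]\n",
              min(x$ce_loss), max(x$ce_loss)))
  invisible(x)
}

#' Look up the feature performance of one SNP
#'
#' @param pm A `performance_matrix`.
#' @param snp_index SNP column index.
#' @return The stored FP, or 0 when the SNP was never fitted.
#' @export
fp_lookup <- function(pm, snp_index) {
  for (k in seq_along(pm$row_snp_indices)) {
    j <- match(snp_index, pm$row_snp_indices[[k]])
    if (!is.na(j)) return(pm$row_fp_values[[k]][j])
  }
  0
}

#' Densify a small performance matrix (testing aid)
#'
#' @param pm A `performance_matrix`.
#' @return Dense K x (P + 1) matrix; last column is the cross-entropy.
#' @export
densify_performance_matrix <- function(pm) {
  k <- length(pm$ce_loss)
  out <- matrix(0, k, pm$p_total + 1L)
  for (r in seq_len(k)) {
    out[r, pm$row_snp_indices[[r]]] <- pm$row_fp_values[[r]]
  }
  out[, pm$p_total + 1L] <- pm$ce_loss
  out
}

#' Persist / load a performance matrix as whitespace-delimited text
#'
#' The on-disk form stores one line per non-zero entry (`row`, `snp_index`,
#' `fp`) plus a cross-entropy table, preserving the O(K * S) contract.
#'
#' @param pm A `performance_matrix`.
#' @param path Output path.
#' @return `path` (writer) or the reconstructed `performance_matrix` (reader).
#' @export
write_performance_matrix <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# performance_matrix K=%d P=%d",
                     length(pm$ce_loss), pm$p_total), con)
  for (k in seq_along(pm$ce_loss)) {
    writeLines(sprintf("CE\t%d\t%.17g", k, pm$ce_loss[k]), con)
    writeLines(sprintf("FP\t%d\t%d\t%.17g", k, pm$row_snp_indices[[k]],
                       pm$row_fp_values[[k]]), con)
  }
  invisible(path)
}

#' @rdname write_performance_matrix
#' @export
read_performance_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("# performance_matrix ", "", lines[1]), " ")[[1]]
  p_total <- as.integer(sub("P=", "", hdr[2]))
  lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, character(1), 1L)
  ce_rows <- parts[tag == "CE"]
  k <- length(ce_rows)
  ce <- numeric(k)
  for (r in ce_rows) ce[as.integer(r[2])] <- as.numeric(r[3])
  idx <- rep(list(integer(0)), k)
  fp <- rep(list(numeric(0)), k)
  fp_rows <- parts[tag == "FP"]
  krow <- vapply(fp_rows, function(r) as.integer(r[2]), integer(1))
  for (kk in seq_len(k)) {
    rows <- fp_rows[krow == kk]
    idx[[kk]] <- vapply(rows, function(r) as.integer(r[3]), integer(1))
    fp[[kk]] <- vapply(rows, function(r) as.numeric(r[4]), numeric(1))
  }
  structure(list(row_snp_indices = idx, row_fp_values = fp, ce_loss = ce,
                 p_total = p_total),
            class = "performance_matrix")
}
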