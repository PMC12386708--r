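#' Feature-selection result container
#'
#' @param relevant_ids Character vector of SNP ids in the relevant set.
#' @param cluster_assignments Factor of per-SNP labels
#'   (`relevant` / `irrelevant`), named by SNP id.
#' @param centroids Cluster centers (matrix, one row per cluster).
#' @param method One of `"tagging"`, `"1d_sra"`, `"md_sra"`.
#' @param diagnostics List of method-specific diagnostics.
#' @return A `feature_selection_result`.
#' @export
feature_selection_result <- function(relevant_ids, cluster_assignments,
                                     centroids, method,
                                     diagnostics = list()) {
  method <- match.arg(method, c("tagging", "1d_sra", "md_sra"))
  structure(list(relevant_ids = as.character(relevant_ids),
                 cluster_assignments = cluster_assignments,
                 centroids = centroids, method = method,
                 diagnostics = diagnostics),
            class = "feature_selection_result")
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat(sprintf("feature_selection_result [%s]: %d of %d SNPs relevant (reduction %.2f%%)\n",
              x$method, length(x$relevant_ids),
              length(x$cluster_assignments),
              reduction_rate(length(x$cluster_assignments),
                             length(x$relevant_ids))))
  invisible(x)
}

#' Assemble the rank-aggregation mixed linear model
#'
#' The aggregation model is `MP = mu + Z a + e` with `MP_k` the reciprocal of
#' reduced model k's cross-entropy, `Z` the sparse K x P matrix of feature
#' performances (the first P columns of the performance matrix), random SNP
#' effects `a ~ N(0, I var_a)` and residuals `e ~ N(0, I var_e)`. The
#' variances are treated as known; only their ratio
#' `lambda = var_e / var_a` enters the solutions.
#'
#' @param pm A [build_performance_matrix()] result.
#' @param var_a Random SNP-effect variance (default 6.5e-5).
#' @param var_e Residual variance (default 1.5e-4).
#' @return An `lmm_system`: `y` (K-vector), `z` (sparse K x P dgCMatrix),
#'   `var_a`, `var_e`, `lambda`.
#' @export
assemble_lmm <- function(pm, var_a = 6.5e-5, var_e = 1.5e-4) {
  stopifnot(var_a > 0, var_e > 0)
  if (any(pm$ce_loss <= 1e-12)) stop("degenerate model fit")
  y <- 1 / pm$ce_loss
  k <- length(y)
  rows <- rep.int(seq_len(k), lengths(pm$row_snp_indices))
  z <- Matrix::sparseMatrix(i = rows, j = unlist(pm$row_snp_indices),
                            x = unlist(pm$row_fp_values),
                            dims = c(k, pm$p_total))
  structure(list(y = y, z = z, var_a = var_a, var_e = var_e,
                 lambda = var_e / var_a),
            class = "lmm_system")
}

#' Solve the mixed model equations by preconditioned conjugate gradients
#'
#' Solves
#' \deqn{\begin{bmatrix} 1'1 & 1'Z \\ Z'1 & Z'Z + \lambda I \end{bmatrix}
#'       \begin{bmatrix} \mu \\ a \end{bmatrix} =
#'       \begin{bmatrix} 1'y \\ Z'y \end{bmatrix}}
#' with a Jacobi (diagonal) preconditioner. `Z'Z` is never formed; every
#' iteration uses two sparse matrix-vector products with `Z`. Convergence is
#' declared when the relative residual norm drops to `tol`.
#'
#' @param sys An [assemble_lmm()] system.
#' @param tol Relative residual tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 10 * (P + 1)).
#' @param intercept Include the general mean? (`FALSE` solves
#'   `(Z'Z + lambda I) a = Z'y` only.)
#' @return An `lmm_solution`: `mu_hat`, `a_hat` (P-vector), `iterations`,
#'   `final_residual` (relative).
#' @export
solve_pcg <- function(sys, tol = 1e-10, max_iter = NULL, intercept = TRUE) {
  if (sys$lambda <= 0) stop("lambda must be positive")
  z <- sys$z
  y <- sys$y
  k <- nrow(z)
  p <- ncol(z)
  if (is.null(max_iter)) max_iter <- 10L * (p + 1L)
  lam <- sys$lambda

  if (intercept) {
    rhs <- c(sum(y), as.numeric(Matrix::crossprod(z, y)))
    diag_a <- c(k, Matrix::colSums(z^2) + lam)
    matvec <- function(x) {
      mu <- x[1]
      a <- x[-1]
      u <- as.numeric(z %*% a)
      c(k * mu + sum(u),
        as.numeric(Matrix::crossprod(z, mu + u)) + lam * a)
    }
  } else {
    rhs <- as.numeric(Matrix::crossprod(z, y))
    diag_a <- Matrix::colSums(z^2) + lam
    matvec <- function(x) {
      as.numeric(Matrix::crossprod(z, as.numeric(z %*% x))) + lam * x
    }
  }
  diag_a[diag_a <= 0] <- 1   # guard (can only happen for k = 0 intercepts)

  rhs_norm <- sqrt(sum(rhs^2))
  x <- numeric(length(rhs))
  if (rhs_norm == 0) {
    return(structure(list(mu_hat = if (intercept) 0 else NA_real_,
                          a_hat = numeric(p), iterations = 0L,
                          final_residual = 0),
                     class = "lmm_solution"))
  }
  r <- rhs
  s <- r / diag_a
  d <- s
  rs <- sum(r * s)
  iter <- 0L
  repeat {
    rel <- sqrt(sum(r^2)) / rhs_norm
    if (rel <= tol) break
    if (iter >= max_iter) {
      stop(sprintf("PCG did not converge in %d iterations (relative residual %.3g)",
                   max_iter, rel))
    }
    q <- matvec(d)
    alpha <- rs / sum(d * q)
    x <- x + alpha * d
    r <- r - alpha * q
    s <- r / diag_a
    rs_new <- sum(r * s)
    d <- s + (rs_new / rs) * d
    rs <- rs_new
    iter <- iter + 1L
  }
  structure(list(mu_hat = if (intercept) x[1] else NA_real_,
                 a_hat = if (intercept) x[-1] else x,
                 iterations = iter,
                 final_residual = sqrt(sum(r^2)) / rhs_norm),
            class = "lmm_solution")
}

two_means <- function(values, seed, n_init = 10) {
  m <- as.matrix(values)
  if (nrow(unique(m)) < 2) stop("no separation")
  set.seed(seed)
  stats::kmeans(m, centers = 2, nstart = n_init)
}

#' Cluster LMM solutions into relevant / irrelevant SNPs
#'
#' One-dimensional 2-means (10 restarts, seeded) on the SNP effect
#' solutions; the cluster whose centroid has the larger absolute value is
#' declared relevant, replacing any arbitrary effect-size cutoff. On a
#' centroid tie the smaller cluster is taken.
#'
#' @param sol A [solve_pcg()] solution.
#' @param seed Integer seed for the k-means restarts.
#' @param snp_ids Optional SNP ids (defaults to index strings).
#' @param unscored Optional integer indices of SNPs never fitted in any
#'   reduced model; they are forced into the irrelevant set with a warning.
#' @return A [feature_selection_result()] with method `"1d_sra"`.
#' @export
select_relevant_1d <- function(sol, seed, snp_ids = NULL, unscored = NULL) {
  a <- sol$a_hat
  if (any(!is.finite(a))) stop("non-finite SNP effect solutions")
  if (is.null(snp_ids)) snp_ids <- as.character(seq_along(a))
  if (length(unique(a)) < 2) stop("no separation")
  km <- two_means(a, seed)
  cent <- as.numeric(km$centers)
  sizes <- km$size
  relevant_cluster <- if (abs(cent[1]) == abs(cent[2])) {
    which.min(sizes)
  } else {
    which.max(abs(cent))
  }
  assign <- ifelse(km$cluster == relevant_cluster, "relevant", "irrelevant")
  if (!is.null(unscored) && length(unscored) > 0) {
    if (any(assign[unscored] == "relevant")) {
      warning("unscored SNPs forced into the irrelevant set")
    }
    assign[unscored] <- "irrelevant"
  }
  assign <- factor(assign, levels = c("relevant", "irrelevant"))
  names(assign) <- snp_ids
  feature_selection_result(
    relevant_ids = snp_ids[assign == "relevant"],
    cluster_assignments = assign,
    centroids = km$centers, method = "1d_sra",
    diagnostics = list(iterations = sol$iterations,
                       final_residual = sol$final_residual,
                       centroids = cent, cluster_sizes = sizes))
}

#' One-dimensional supervised rank aggregation, end to end
#'
#' Runs the full pipeline on a labeled dataset: random partition into
#' reduced models of `s` SNPs, penalized multinomial logit per block,
#' performance-matrix assembly, mixed-model aggregation solved by PCG, and
#' 1-D 2-means selection.
#'
#' @param ds A labeled, QC'd [genotype_dataset()].
#' @param s SNPs per reduced model (default 250).
#' @param seed Master seed.
#' @param var_a,var_e Aggregation-model variances (defaults 6.5e-5 / 1.5e-4).
#' @param tol PCG relative residual tolerance.
#' @param drop_remainder Discard the incomplete tail block?
#' @param ridge Ridge weight for the block fits.
#' @param fp_mode Feature-performance mode, `"abs_max"` (default) or
#'   `"signed_max"`.
#' @return A [feature_selection_result()] with method `"1d_sra"`; its
#'   diagnostics carry the solver trace and the performance matrix.
#' @export
select_1d_sra <- function(ds, s = 250, seed = 1, var_a = 6.5e-5,
                          var_e = 1.5e-4, tol = 1e-10,
                          drop_remainder = FALSE, ridge = 0.5,
                          fp_mode = "abs_max") {
  p <- n_snps(ds)
  part <- partition_features(p, s, seed = derive_seed(seed, 0L),
                             drop_remainder = drop_remainder)
  fits <- fit_all_blocks(ds, part, ridge = ridge, fp_mode = fp_mode)
  pm <- build_performance_matrix(fits, part)
  sys <- assemble_lmm(pm, var_a = var_a, var_e = var_e)
  sol <- solve_pcg(sys, tol = tol)
  unscored <- setdiff(seq_len(p), unlist(part$blocks))
  res <- select_relevant_1d(sol, seed = derive_seed(seed, 1L),
                            snp_ids = ds$snp_ids, unscored = unscored)
  res$diagnostics$performance_matrix <- pm
  res$diagnostics$mu_hat <- sol$mu_hat
  res
}
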