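make_pm <- function(idx, fp, ce, p_total) {
  structure(list(row_snp_indices = idx, row_fp_values = fp, ce_loss = ce,
                 p_total = p_total), class = "performance_matrix")
}

test_that("the aggregation system uses reciprocal cross-entropy and lambda = var_e/var_a", {
  pm <- make_pm(list(1:2, 3:4), list(c(1, 2), c(3, 4)), c(0.5, 2.0), 4L)
  sys <- assemble_lmm(pm)
  expect_equal(sys$y, c(2.0, 0.5))
  expect_equal(sys$lambda, 1.5e-4 / 6.5e-5)
  expect_equal(sys$lambda, 2.3077, tolerance = 1e-4)
  expect_equal(Matrix::nnzero(sys$z), 4L)
  pm_bad <- make_pm(list(1L), list(1), 1e-13, 1L)
  expect_error(assemble_lmm(pm_bad), "degenerate")
})

test_that("PCG solves a zero system trivially and a tiny system exactly", {
  pm0 <- make_pm(list(1:2), list(c(1, 1)), 1, 2L)
  sys0 <- assemble_lmm(pm0, var_a = 1, var_e = 1)
  sys0$y <- 0
  sol0 <- solve_pcg(sys0)
  expect_equal(sol0$mu_hat, 0)
  expect_equal(sol0$a_hat, c(0, 0))

  # Z = [[1,0],[0,1],[1,1]], y = (1,2,3), lambda = 1, no intercept
  pm1 <- make_pm(list(1L, 2L, 1:2), list(1, 1, c(1, 1)), c(1, 1 / 2, 1 / 3), 2L)
  sys1 <- assemble_lmm(pm1, var_a = 1, var_e = 1)
  sol1 <- solve_pcg(sys1, tol = 1e-12, intercept = FALSE)
  expect_equal(sol1$a_hat, c(0.875, 1.375), tolerance = 1e-9)
})

test_that("PCG matches a dense mixed-model-equation solve on random systems", {
  set.seed(42)
  for (rep in 1:3) {
    k <- 50; p <- 20
    idx <- lapply(seq_len(k), function(i) sort(sample.int(p, 5)))
    fp <- lapply(idx, function(i) stats::rnorm(5))
    ce <- stats::runif(k, 0.3, 3)
    pm <- make_pm(idx, fp, ce, p)
    sys <- assemble_lmm(pm)
    sol <- solve_pcg(sys, tol = 1e-12)
    z <- as.matrix(sys$z)
    lhs <- rbind(c(k, colSums(z)),
                 cbind(colSums(z), crossprod(z) + diag(sys$lambda, p)))
    rhs <- c(sum(sys$y), crossprod(z, sys$y))
    direct <- solve(lhs, rhs)
    expect_equal(c(sol$mu_hat, sol$a_hat), unname(direct), tolerance = 1e-8)
  }
})

test_that("PCG satisfies its residual certificate and depends on variances only via lambda", {
  set.seed(17)
  k <- 30; p <- 12
  idx <- lapply(seq_len(k), function(i) sort(sample.int(p, 4)))
  fp <- lapply(idx, function(i) stats::rnorm(4))
  pm <- make_pm(idx, fp, stats::runif(k, 0.5, 2), p)
  sys <- assemble_lmm(pm, var_a = 6.5e-5, var_e = 1.5e-4)
  sol <- solve_pcg(sys, tol = 1e-10)
  z <- as.matrix(sys$z)
  x <- c(sol$mu_hat, sol$a_hat)
  lhs <- rbind(c(k, colSums(z)),
               cbind(colSums(z), crossprod(z) + diag(sys$lambda, p)))
  rhs <- c(sum(sys$y), crossprod(z, sys$y))
  expect_lt(sqrt(sum((lhs %*% x - rhs)^2)), 1e-10 * sqrt(sum(rhs^2)) * 1.01)

  scaled <- assemble_lmm(pm, var_a = 6.5e-4, var_e = 1.5e-3)
  sol10 <- solve_pcg(scaled, tol = 1e-10)
  expect_equal(sol10$a_hat, sol$a_hat, tolerance = 1e-8)
})

test_that("the SNP-effect norm shrinks as lambda grows", {
  set.seed(23)
  k <- 20; p <- 8
  idx <- lapply(seq_len(k), function(i) sort(sample.int(p, 3)))
  fp <- lapply(idx, function(i) stats::rnorm(3))
  pm <- make_pm(idx, fp, stats::runif(k, 0.5, 2), p)
  norms <- sapply(c(0.1, 1, 10, 100), function(lam) {
    sys <- assemble_lmm(pm, var_a = 1, var_e = lam)
    sqrt(sum(solve_pcg(sys, tol = 1e-12)$a_hat^2))
  })
  expect_true(all(diff(norms) < 1e-12))
})

test_that("1-D clustering selects the large-magnitude cluster", {
  sol <- structure(list(mu_hat = 0, a_hat = c(0.0, 0.01, 0.02, 10.0, 10.1),
                        iterations = 1L, final_residual = 0),
                   class = "lmm_solution")
  res <- select_relevant_1d(sol, seed = 1)
  expect_setequal(res$relevant_ids, c("4", "5"))

  flipped <- sol
  flipped$a_hat <- -sol$a_hat
  res_f <- select_relevant_1d(flipped, seed = 1)
  expect_setequal(res_f$relevant_ids, res$relevant_ids)

  degenerate <- sol
  degenerate$a_hat <- rep(1, 5)
  expect_error(select_relevant_1d(degenerate, seed = 1), "no separation")
})

test_that("1-D 2-means equals exhaustive partition minimization on small inputs", {
  set.seed(5)
  for (rep in 1:5) {
    a <- round(stats::rnorm(10), 2)
    sol <- structure(list(mu_hat = 0, a_hat = a, iterations = 1L,
                          final_residual = 0), class = "lmm_solution")
    res <- select_relevant_1d(sol, seed = rep)
    km_ss <- partition_ss(matrix(a, ncol = 1),
                          as.integer(res$cluster_assignments))
    brute <- brute_two_means(matrix(a, ncol = 1))
    expect_equal(km_ss, brute$ss, tolerance = 1e-9)
  }
})

test_that("unscored SNPs are forced into the irrelevant set", {
  sol <- structure(list(mu_hat = 0, a_hat = c(5, 5.1, 0.1, 0, 0),
                        iterations = 1L, final_residual = 0),
                   class = "lmm_solution")
  res <- select_relevant_1d(sol, seed = 2, unscored = 4:5)
  expect_true(all(res$cluster_assignments[4:5] == "irrelevant"))
})
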