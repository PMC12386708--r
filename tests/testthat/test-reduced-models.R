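test_that("feature partition covers full-scale arithmetic and edge cases", {
  part <- partition_features(11915233, 250, seed = 1, drop_remainder = TRUE)
  expect_length(part$blocks, 47660L)
  expect_true(all(lengths(part$blocks) == 250L))

  one <- partition_features(10, 10, seed = 3)
  expect_length(one$blocks, 1L)
  expect_setequal(one$blocks[[1]], 1:10)

  tail_kept <- partition_features(1000, 250, seed = 9, drop_remainder = FALSE)
  expect_length(tail_kept$blocks, 4L)
  expect_setequal(unlist(tail_kept$blocks), 1:1000)

  expect_error(partition_features(10, 11, seed = 1), "1 <= s <= p_total")
})

test_that("partition blocks are pairwise disjoint for either remainder mode", {
  for (drop in c(TRUE, FALSE)) {
    part <- partition_features(103, 10, seed = 4, drop_remainder = drop)
    all_idx <- unlist(part$blocks)
    expect_false(anyDuplicated(all_idx) > 0)
    expect_length(all_idx, if (drop) 100L else 103L)
  }
})

test_that("cross-entropy matches closed forms", {
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy(factor(c("a", "b", "c")), perfect), 0)
  half <- matrix(0.5, 2, 2)
  expect_equal(cross_entropy(factor(c("a", "b")), half), log(2),
               tolerance = 1e-12)
  unif5 <- matrix(0.2, 4, 5)
  expect_equal(cross_entropy(factor(c("a", "b", "c", "d"),
                                    levels = letters[1:5]), unif5),
               log(5), tolerance = 1e-12)
  expect_error(cross_entropy(factor(c("a", "b")), matrix(0.5, 3, 2)),
               "shape mismatch")
  expect_error(cross_entropy(factor(c("a", "b")), matrix(c(0.9, 0.3,
                                                           0.2, 0.3), 2, 2)),
               "sum to 1")
})

test_that("all-constant SNP blocks reduce to the intercept-only cross-entropy", {
  labels <- rep(c("a", "b", "c", "d", "e"), each = 4)
  ds <- toy_dataset(list(rep(1L, 20), rep(2L, 20)), labels = labels)
  fit <- fit_block_model(ds, 1:2, ridge = 1e-6)
  expect_lt(max(abs(fit$beta_hat)), 1e-3)
  expect_equal(fit$ce_loss, log(5), tolerance = 1e-3)
})

test_that("a perfectly separating SNP drives cross-entropy to ~0 under weak ridge", {
  labels <- rep(c("a", "b"), each = 5)
  g <- c(rep(0L, 5), rep(2L, 5))
  ds <- toy_dataset(list(g), labels = labels)
  fit <- fit_block_model(ds, 1, ridge = 1e-6)
  expect_lt(fit$ce_loss, 0.01)
})

test_that("block fits agree with an independent penalized multinomial fit", {
  skip_if_not_installed("nnet")
  # 2-class dosage toy; quasi-separated, so under the near-zero ridge the
  # optimum is flat in coefficient space: optimizers agree on the fitted
  # probabilities and on the penalized objective, which is what we compare.
  # (A well-conditioned coefficient comparison follows at moderate ridge.)
  ds <- toy_dataset(list(c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L)),
                    labels = c("c1", "c1", "c1", "c1", "c2", "c2", "c2", "c2"))
  y <- factor(c(rep("c1", 4), rep("c2", 4)), levels = c("c2", "c1"))
  pen_obj <- function(alpha, beta, ridge) {
    eta <- alpha + beta * ds$dosages[, 1]
    p1 <- 1 / (1 + exp(-eta))      # P(c1); reference class c2
    ll <- sum(log(ifelse(ds$labels == "c1", p1, 1 - p1)))
    -ll + ridge * (alpha^2 + beta^2)
  }
  for (ridge in c(1e-6, 0.01)) {
    fit <- fit_block_model(ds, 1, ridge = ridge)
    oracle <- nnet::multinom(y ~ x, data = data.frame(x = ds$dosages[, 1]),
                             decay = ridge, reltol = 1e-16, maxit = 2000,
                             trace = FALSE)
    obj_mine <- unname(pen_obj(fit$alpha_hat, fit$beta_hat[1, 1], ridge))
    obj_oracle <- unname(pen_obj(coef(oracle)[1], coef(oracle)[2], ridge))
    expect_lte(obj_mine, obj_oracle + 1e-6)   # at least as converged
    expect_equal(obj_mine, obj_oracle, tolerance = 1e-4)
    p_oracle <- as.numeric(fitted(oracle))    # P(c1), the non-reference level
    expect_equal(unname(fit$probs[, "c1"]), p_oracle, tolerance = 1e-3)
    if (ridge >= 0.01) {
      expect_equal(unname(fit$alpha_hat), unname(coef(oracle)[1]),
                   tolerance = 1e-4)
      expect_equal(unname(fit$beta_hat[1, 1]), unname(coef(oracle)[2]),
                   tolerance = 1e-4)
    }
  }

  # multi-class random toy with noticeable ridge
  set.seed(42)
  dsm <- toy_dataset(lapply(1:3, function(i) sample(0:2, 30, replace = TRUE)),
                     labels = sample(c("a", "b", "c"), 30, replace = TRUE))
  fitm <- fit_block_model(dsm, 1:3, ridge = 0.5)
  ym <- factor(dsm$labels, levels = c("c", "a", "b"))
  om <- nnet::multinom(ym ~ ., data = data.frame(dsm$dosages), decay = 0.5,
                       reltol = 1e-14, maxit = 1000, trace = FALSE)
  co <- coef(om)[c("a", "b"), ]
  expect_equal(unname(fitm$alpha_hat), unname(co[, 1]), tolerance = 1e-4)
  expect_equal(unname(fitm$beta_hat), unname(co[, -1]), tolerance = 1e-4)
})

test_that("feature performance takes the absolute or signed coefficient maximum", {
  set.seed(7)
  ds <- toy_dataset(lapply(1:4, function(i) sample(0:2, 30, replace = TRUE)),
                    labels = sample(c("a", "b", "c"), 30, replace = TRUE))
  fit_abs <- fit_block_model(ds, 1:4, ridge = 0.5, fp_mode = "abs_max")
  fit_sgn <- fit_block_model(ds, 1:4, ridge = 0.5, fp_mode = "signed_max")
  expect_equal(fit_abs$feature_performance,
               apply(abs(fit_abs$beta_hat), 2, max))
  expect_equal(fit_sgn$feature_performance, apply(fit_sgn$beta_hat, 2, max))
  expect_true(all(fit_abs$feature_performance >= 0))
})

test_that("block fits are invariant to SNP order and individual order", {
  set.seed(11)
  ds <- toy_dataset(lapply(1:5, function(i) sample(0:2, 40, replace = TRUE)),
                    labels = sample(c("x", "y", "z"), 40, replace = TRUE))
  f1 <- fit_block_model(ds, c(1, 3, 5), ridge = 0.5)
  f2 <- fit_block_model(ds, c(5, 1, 3), ridge = 0.5)
  expect_equal(f1$ce_loss, f2$ce_loss, tolerance = 1e-9)
  expect_equal(sort(f1$feature_performance), sort(f2$feature_performance),
               tolerance = 1e-7)

  perm <- sample(40)
  dsp <- subset_dataset(ds, samples = perm)
  f3 <- fit_block_model(dsp, c(1, 3, 5), ridge = 0.5)
  expect_equal(f3$ce_loss, f1$ce_loss, tolerance = 1e-9)
  expect_equal(f3$beta_hat, f1$beta_hat, tolerance = 1e-7)
})

test_that("single-class labels are refused", {
  ds <- toy_dataset(list(sample(0:2, 6, replace = TRUE)))
  ds$labels <- factor(rep("only", 6))
  expect_error(fit_block_model(ds, 1), "single class")
})

test_that("performance matrix stores exactly one FP entry per fitted SNP", {
  set.seed(3)
  ds <- toy_dataset(lapply(1:6, function(i) sample(0:2, 30, replace = TRUE)),
                    labels = sample(c("a", "b"), 30, replace = TRUE))
  part <- partition_features(6, 3, seed = 2)
  fits <- fit_all_blocks(ds, part, ridge = 0.5)
  pm <- build_performance_matrix(fits, part)
  expect_equal(sum(lengths(pm$row_snp_indices)), 6L)
  expect_length(pm$ce_loss, 2L)
  all_idx <- unlist(pm$row_snp_indices)
  expect_false(anyDuplicated(all_idx) > 0)

  dup_fits <- fits
  dup_fits[[2]]$block <- fits[[1]]$block
  expect_error(build_performance_matrix(dup_fits, part), "duplicate")
})

test_that("unsampled SNPs have zero FP and densified C matches brute force", {
  set.seed(8)
  ds <- toy_dataset(lapply(1:7, function(i) sample(0:2, 30, replace = TRUE)),
                    labels = sample(c("a", "b"), 30, replace = TRUE))
  part <- partition_features(7, 3, seed = 5, drop_remainder = TRUE)
  fits <- fit_all_blocks(ds, part, ridge = 0.5)
  pm <- build_performance_matrix(fits, part)
  left_out <- setdiff(1:7, unlist(part$blocks))
  expect_length(left_out, 1L)
  expect_equal(fp_lookup(pm, left_out), 0)

  dense <- densify_performance_matrix(pm)
  expect_equal(dim(dense), c(2L, 8L))
  brute <- matrix(0, 2, 8)
  for (k in 1:2) {
    brute[k, part$blocks[[k]]] <- fits[[k]]$feature_performance
    brute[k, 8] <- fits[[k]]$ce_loss
  }
  expect_equal(dense, brute)
})

test_that("performance matrix text persistence round-trips exactly", {
  set.seed(13)
  ds <- toy_dataset(lapply(1:6, function(i) sample(0:2, 20, replace = TRUE)),
                    labels = sample(c("a", "b"), 20, replace = TRUE))
  part <- partition_features(6, 2, seed = 2)
  pm <- build_performance_matrix(fit_all_blocks(ds, part, ridge = 0.5), part)
  path <- tempfile()
  write_performance_matrix(pm, path)
  rt <- read_performance_matrix(path)
  expect_equal(rt$ce_loss, pm$ce_loss)
  expect_equal(rt$row_snp_indices, lapply(pm$row_snp_indices, as.integer))
  expect_equal(rt$row_fp_values, pm$row_fp_values)
  expect_equal(rt$p_total, pm$p_total)
})
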