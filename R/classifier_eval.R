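#' Focal-loss class weights
#'
#' `alpha_b = N / (B * g_b)` with `g_b` the training count of class b:
#' balanced classes get weight 1, rare classes more.
#'
#' @param n Total number of individuals.
#' @param class_counts Integer vector of per-class counts summing to `n`.
#' @return Numeric vector of class weights.
#' @export
focal_alpha <- function(n, class_counts) {
  if (any(class_counts <= 0)) stop("every class needs a positive count")
  if (sum(class_counts) != n) stop("class counts must sum to n")
  n / (length(class_counts) * class_counts)
}

#' Focal-loss configuration
#'
#' @param n Training-set size.
#' @param class_counts Per-class training counts.
#' @param gamma Focusing exponent (fixed default 2).
#' @return A `focal_loss_config` with `gamma` and `alphas`.
#' @export
focal_loss_config <- function(n, class_counts, gamma = 2) {
  structure(list(gamma = gamma, alphas = focal_alpha(n, class_counts)),
            class = "focal_loss_config")
}

#' Focal loss of predicted class probabilities
#'
#' Mean over individuals of
#' `alpha_true * (1 - p_true)^gamma * (-log p_true)`; the class weighting
#' and the `(1 - p)^gamma` factor down-weight easy, well-represented
#' examples. With `gamma = 0` and unit weights this reduces to the
#' cross-entropy.
#'
#' @param probs N x B matrix of class probabilities (columns named by class
#'   or ordered as the label levels).
#' @param true_labels Factor/character vector of N true classes.
#' @param cfg A [focal_loss_config()].
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(probs, true_labels, cfg) {
  if (!is.factor(true_labels)) true_labels <- factor(true_labels)
  if (nrow(probs) != length(true_labels)) stop("shape mismatch")
  if (length(cfg$alphas) != ncol(probs)) stop("shape mismatch")
  col <- if (!is.null(colnames(probs))) {
    match(as.character(true_labels), colnames(probs))
  } else {
    as.integer(true_labels)
  }
  if (anyNA(col)) stop("labels not covered by probability columns")
  p_true <- pmax(probs[cbind(seq_along(col), col)], 1e-15)
  mean(cfg$alphas[col] * (1 - p_true)^cfg$gamma * (-log(p_true)))
}

#' Macro F1 score from a confusion matrix
#'
#' Macro-averaged precision and recall are combined by the harmonic mean:
#' `Precision = mean_b TP_b / (TP_b + FP_b)`,
#' `Recall = mean_b TP_b / (TP_b + FN_b)`,
#' `F1 = 2 P R / (P + R)`, reported as a percentage. A class with zero
#' predicted (or actual) count contributes 0 to the respective average.
#'
#' @param confusion Square B x B matrix, rows = true class, columns =
#'   predicted class.
#' @return Macro F1 in percent.
#' @export
macro_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix not square")
  if (any(confusion < 0)) stop("negative confusion counts")
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  true_tot <- rowSums(confusion)
  prec <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec <- ifelse(true_tot > 0, tp / true_tot, 0)
  p <- mean(prec)
  r <- mean(rec)
  if (p + r == 0) return(0)
  100 * 2 * p * r / (p + r)
}

#' Macro one-vs-rest AUC
#'
#' Per class, the ROC AUC of that class's score column against the binary
#' "is this class" labels, computed by the rank-sum (Mann-Whitney)
#' formulation with ties credited 0.5; classes without both a positive and
#' a negative example are skipped with a warning. The per-class AUCs are
#' averaged.
#'
#' @param scores N x B matrix of class scores (probabilities or logits).
#' @param true_labels Factor/character vector of N true classes.
#' @return Macro AUC in [0, 1].
#' @export
macro_auc <- function(scores, true_labels) {
  if (!is.factor(true_labels)) true_labels <- factor(true_labels)
  if (nrow(scores) != length(true_labels)) stop("shape mismatch")
  classes <- levels(true_labels)
  col <- if (!is.null(colnames(scores))) {
    match(classes, colnames(scores))
  } else {
    seq_along(classes)
  }
  aucs <- numeric(0)
  for (k in seq_along(classes)) {
    pos <- true_labels == classes[k]
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      warning("class ", classes[k], " lacks positives or negatives; skipped")
      next
    }
    rk <- rank(scores[, col[k]])
    aucs <- c(aucs, (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (length(aucs) == 0) stop("all classes skipped")
  mean(aucs)
}

confusion_matrix <- function(true_labels, pred_labels, classes) {
  table(factor(true_labels, levels = classes),
        factor(pred_labels, levels = classes))
}

stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    members <- sample(which(y == cl))
    fold[members] <- rep_len(seq_len(n_folds), length(members))
  }
  if (any(vapply(seq_len(n_folds),
                 function(f) any(table(y[fold != f]) == 0), logical(1)))) {
    stop("a fold lacks a class")
  }
  fold
}

#' Stratified K-fold cross-validated CNN training and evaluation
#'
#' Per fold, a fresh seeded classifier is trained with Adam on the focal
#' loss and evaluated on the held-out individuals by macro F1 and macro
#' one-vs-rest AUC. An optional independent test set is scored by a model
#' trained on all of `ds_selected`.
#'
#' @param ds_selected A labeled [genotype_dataset()] already restricted to
#'   the selected SNPs.
#' @param cfg A [cnn_config()].
#' @param n_folds Number of folds (default 5).
#' @param test_ds Optional held-out labeled `genotype_dataset` on the same
#'   SNPs.
#' @param keep_model Also train (and return) a model on all of
#'   `ds_selected` even without a test set (needed for attributions).
#' @return A `metrics_report`: `per_fold` data frame (macro_f1, macro_auc),
#'   `macro_f1` / `macro_auc` (validation means), `sd_f1`, `sd_auc`,
#'   `confusion` (summed validation confusion), and `test` metrics when a
#'   test set was given.
#' @export
train_cv <- function(ds_selected, cfg = cnn_config(), n_folds = 5,
                     test_ds = NULL, keep_model = FALSE) {
  if (is.null(ds_selected$labels)) stop("labels required")
  stopifnot(n_folds >= 2)
  y <- ds_selected$labels
  x <- ds_selected$dosages
  storage.mode(x) <- "double"
  classes <- levels(y)
  b <- length(classes)
  fold <- stratified_folds(y, n_folds, derive_seed(cfg$seed, 11L))
  per_fold <- data.frame(fold = seq_len(n_folds), macro_f1 = NA_real_,
                         macro_auc = NA_real_)
  confusion <- matrix(0L, b, b, dimnames = list(classes, classes))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, 100L + f)
    model <- build_classifier(ncol(x), b, fold_cfg)
    model <- train_classifier(model, x[tr, , drop = FALSE], y[tr])
    probs <- predict_classifier(model, x[!tr, , drop = FALSE])
    colnames(probs) <- classes
    pred <- classes[max.col(probs, ties.method = "first")]
    cm <- confusion_matrix(y[!tr], pred, classes)
    confusion <- confusion + as.matrix(cm)
    per_fold$macro_f1[f] <- macro_f1(cm)
    per_fold$macro_auc[f] <- macro_auc(probs, y[!tr])
  }
  report <- structure(
    list(per_fold = per_fold,
         macro_f1 = mean(per_fold$macro_f1),
         macro_auc = mean(per_fold$macro_auc),
         sd_f1 = stats::sd(per_fold$macro_f1),
         sd_auc = stats::sd(per_fold$macro_auc),
         confusion = confusion, classes = classes),
    class = "metrics_report")
  if (!is.null(test_ds) || keep_model) {
    full_cfg <- cfg
    full_cfg$seed <- derive_seed(cfg$seed, 200L)
    model <- build_classifier(ncol(x), b, full_cfg)
    model <- train_classifier(model, x, y)
    report$model <- model
  }
  if (!is.null(test_ds)) {
    xt <- test_ds$dosages
    storage.mode(xt) <- "double"
    probs <- predict_classifier(model, xt)
    colnames(probs) <- classes
    pred <- classes[max.col(probs, ties.method = "first")]
    cm <- confusion_matrix(test_ds$labels, pred, classes)
    report$test <- list(macro_f1 = macro_f1(cm),
                        macro_auc = macro_auc(probs, test_ds$labels),
                        confusion = as.matrix(cm))
  }
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: validation macro F1 = %.2f%% (sd %.2f), macro AUC = %.4f (sd %.4f)\n",
              x$macro_f1, x$sd_f1, x$macro_auc, x$sd_auc))
  if (!is.null(x$test)) {
    cat(sprintf("  test macro F1 = %.2f%%, macro AUC = %.4f\n",
                x$test$macro_f1, x$test$macro_auc))
  }
  invisible(x)
}

#' Aggregate per-sample attributions into per-SNP importance scores
#'
#' For SNP p the score is the mean over individuals of the class-wise
#' maximum attribution, `score_p = (1/N) sum_i max_b attr[i, b, p]`.
#'
#' @param per_sample_attr N x B x P array of attributions (any backend,
#'   e.g. [compute_attributions()]).
#' @param snp_ids Optional P SNP ids for the report.
#' @param backend Label recorded in the report.
#' @return An `attribution_report`: `per_snp_score` (named P-vector) and
#'   `backend`.
#' @export
aggregate_attributions <- function(per_sample_attr, snp_ids = NULL,
                                   backend = "gradient_input") {
  d <- dim(per_sample_attr)
  if (length(d) != 3) stop("attribution tensor must be N x B x P")
  score <- apply(per_sample_attr, c(1, 3), max)   # N x P class-wise max
  per_snp <- colMeans(score)
  if (!is.null(snp_ids)) {
    if (length(snp_ids) != d[3]) stop("shape mismatch")
    names(per_snp) <- snp_ids
  }
  structure(list(per_snp_score = per_snp, backend = backend),
            class = "attribution_report")
}
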