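pipeline_schema <- c("out_dir", "seed", "simulate", "input", "qc", "split",
                     "select", "train", "attribute")

validate_pipeline_config <- function(config) {
  bad <- setdiff(names(config), pipeline_schema)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config key 'out_dir' is required",
                                    call. = FALSE)
  if (is.null(config$simulate) && is.null(config$input)) {
    stop("config needs either 'simulate' or 'input'", call. = FALSE)
  }
  invisible(config)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the end-to-end selection / classification pipeline
#'
#' Executes the requested stages in dependency order: simulate (or load a
#' VCF + labels), QC filter, stratified train/test split, feature selection
#' by one of `tagging`, `1d_sra`, `md_sra` or `random` (an equal-size random
#' baseline needs `select$n_random`), CNN training with cross-validation,
#' and attribution aggregation. Every run writes a `manifest.json`
#' describing inputs, seeds, configuration, stage timings and every output
#' file; rerunning an identical config reproduces the outputs.
#'
#' @param config A named list or a path to a JSON config file. Recognized
#'   keys: `out_dir`, `seed`, `simulate` (arguments of [sim_config()]),
#'   `input` (`vcf`, `labels`), `qc` (arguments of [qc_config()]), `split`
#'   (`test_fraction`), `select` (`method`, plus method arguments), `train`
#'   (arguments of [cnn_config()] plus `n_folds`), `attribute` (flag).
#' @return List with the selection result, the metrics report (if trained)
#'   and the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("sraselect")),
                   timings = list(), outputs = list())
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- if (is.null(sim_args$seed)) seed else sim_args$seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(cfg)
    ds <- sim$dataset
    truth <- sim$truth
    stage_log("simulate", "N=%d P=%d", n_individuals(ds), n_snps(ds))
  } else {
    ds <- read_vcf(config$input$vcf, config$input$labels)
    truth <- NULL
    stage_log("load", "N=%d P=%d from %s", n_individuals(ds), n_snps(ds),
              config$input$vcf)
  }
  manifest$timings$load <- tic() - t0

  t0 <- tic()
  qc_args <- if (is.null(config$qc)) list() else config$qc
  ds <- apply_qc(ds, do.call(qc_config, qc_args))
  stage_log("filter", "P=%d after QC (removed: %s)", n_snps(ds),
            paste(attr(ds, "qc_removed"), collapse = "/"))
  manifest$timings$qc <- tic() - t0

  test_ds <- NULL
  if (!is.null(config$split) && !is.null(ds$labels)) {
    sp <- split_train_test(ds, config$split$test_fraction,
                           seed = derive_seed(seed, 3L))
    ds <- sp$train
    test_ds <- sp$test
    stage_log("split", "train N=%d, test N=%d", n_individuals(ds),
              n_individuals(test_ds))
  }

  t0 <- tic()
  sel_cfg <- config$select
  if (is.null(sel_cfg)) sel_cfg <- list(method = "tagging")
  method <- match.arg(sel_cfg$method,
                      c("tagging", "1d_sra", "md_sra", "random"))
  sel <- switch(method,
    tagging = select_tag_snps(ds, tag_config(
      window_bp = sel_cfg$window_bp %||% 100000L,
      r2_max = sel_cfg$r2_max %||% 0.5)),
    "1d_sra" = select_1d_sra(ds, s = sel_cfg$s %||% 250,
      seed = derive_seed(seed, 4L),
      var_a = sel_cfg$var_a %||% 6.5e-5,
      var_e = sel_cfg$var_e %||% 1.5e-4,
      tol = sel_cfg$tol %||% 1e-10),
    md_sra = select_md_sra(ds, w_repeats = sel_cfg$w_repeats %||% 5,
      s = sel_cfg$s %||% 250, seed = derive_seed(seed, 5L)),
    random = {
      n_random <- sel_cfg$n_random
      if (is.null(n_random)) stop("select$n_random required for method 'random'")
      set.seed(derive_seed(seed, 6L))
      ids <- ds$snp_ids[sort(sample.int(n_snps(ds), n_random))]
      assign <- factor(ifelse(ds$snp_ids %in% ids, "relevant", "irrelevant"),
                       levels = c("relevant", "irrelevant"))
      names(assign) <- ds$snp_ids
      feature_selection_result(ids, assign, matrix(numeric(0), 0, 0),
                               method = "tagging",
                               diagnostics = list(baseline = "random"))
    })
  stage_log("select", "%s kept %d of %d SNPs", method,
            length(sel$relevant_ids), n_snps(ds))
  relevant_path <- file.path(out_dir, "relevant_snps.txt")
  writeLines(sel$relevant_ids, relevant_path)
  manifest$outputs$relevant_snps <- relevant_path
  manifest$timings$select <- tic() - t0

  report <- NULL
  if (!is.null(config$train) && !identical(config$train$enabled, FALSE)) {
    t0 <- tic()
    train_args <- config$train
    train_args$enabled <- NULL
    n_folds <- train_args$n_folds %||% 5
    train_args$n_folds <- NULL
    train_args$seed <- train_args$seed %||% derive_seed(seed, 8L)
    ccfg <- do.call(cnn_config, train_args)
    ds_sel <- subset_dataset(ds, snps = sel$relevant_ids)
    test_sel <- if (!is.null(test_ds)) {
      subset_dataset(test_ds, snps = sel$relevant_ids)
    }
    report <- train_cv(ds_sel, ccfg, n_folds = n_folds, test_ds = test_sel,
                       keep_model = isTRUE(config$attribute))
    stage_log("train", "validation macro F1 %.2f%%, macro AUC %.4f",
              report$macro_f1, report$macro_auc)
    metrics_path <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(list(
      macro_f1 = report$macro_f1, macro_auc = report$macro_auc,
      sd_f1 = report$sd_f1, sd_auc = report$sd_auc,
      per_fold = report$per_fold,
      test = if (!is.null(report$test)) {
        list(macro_f1 = report$test$macro_f1,
             macro_auc = report$test$macro_auc)
      }), metrics_path, auto_unbox = TRUE, digits = NA)
    confusion_path <- file.path(out_dir, "confusion.tsv")
    utils::write.table(report$confusion, confusion_path, sep = "\t",
                       quote = FALSE, col.names = NA)
    manifest$outputs$metrics <- metrics_path
    manifest$outputs$confusion <- confusion_path
    manifest$timings$train <- tic() - t0

    if (isTRUE(config$attribute) && !is.null(report$model)) {
      t0 <- tic()
      attr_arr <- compute_attributions(report$model, ds_sel$dosages)
      rep_attr <- aggregate_attributions(attr_arr, snp_ids = ds_sel$snp_ids)
      attr_path <- file.path(out_dir, "attributions.tsv")
      utils::write.table(
        data.frame(snp_id = names(rep_attr$per_snp_score),
                   score = as.numeric(rep_attr$per_snp_score)),
        attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$outputs$attributions <- attr_path
      manifest$timings$attribute <- tic() - t0
    }
  }

  if (!is.null(truth)) {
    manifest$truth_recall <- mean(truth$signal_snp_ids %in% sel$relevant_ids)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest$outputs$manifest <- manifest_path
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  stage_log("done", "manifest at %s", manifest_path)
  invisible(list(selection = sel, metrics = report, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
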