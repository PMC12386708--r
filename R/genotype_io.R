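#' Quality-control configuration
#'
#' Defaults follow common whole-genome-sequence practice for breed panels:
#' SNPs are removed when their call rate falls below 95%, their minor allele
#' frequency falls below 5%, or they carry more than one ALT allele. Both
#' frequency filters are strict inequalities for removal, so a SNP at exactly
#' the threshold is retained.
#'
#' @param call_rate_min Minimum fraction of non-missing genotypes, in [0, 1].
#' @param maf_min Minimum minor allele frequency, in [0, 0.5].
#' @param biallelic_only Drop SNPs flagged as multiallelic?
#' @return A `qc_config` list.
#' @export
qc_config <- function(call_rate_min = 0.95, maf_min = 0.05,
                      biallelic_only = TRUE) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "qc_config")
}

#' Read genotypes from a VCF file with a sample-label table
#'
#' Parses the GT field of a VCF 4.x file into ALT-allele dosages (0/0 -> 0,
#' 0/1 -> 1, 1/1 -> 2; phased "|" and unphased "/" separators both accepted;
#' "./." becomes a missing value). Records whose ALT field contains a comma
#' (multiallelic) are dropped before dosage parsing, and the number dropped is
#' reported in the `n_multiallelic_dropped` attribute.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param labels_path Optional path to a 2-column TSV (sample_id, class).
#'   Every VCF sample must be present; extra rows are ignored.
#' @return A [genotype_dataset()]; missing genotypes are `NA` until
#'   [apply_qc()] is run.
#' @export
read_vcf <- function(path, labels_path = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  sample_ids <- colnames(vcf@gt)[-1]
  if (is.null(sample_ids)) sample_ids <- character(0)
  n <- length(sample_ids)
  keep <- rep(TRUE, nrow(fix))
  if (nrow(fix) > 0) keep <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  p <- nrow(fix)

  if (p > 0 && n > 0) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    # strip anything after the genotype call itself
    first <- substr(gt, 1L, 1L)
    sep <- substr(gt, 2L, 2L)
    second <- substr(gt, 3L, 3L)
    dos <- matrix(NA_integer_, nrow = n, ncol = p)
    ok_allele <- function(a) a %in% c("0", "1", ".")
    bad <- !(ok_allele(first) & ok_allele(second) & sep %in% c("/", "|")) &
      !is.na(gt)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("malformed GT '%s' at record %s:%s sample %s",
                   gt[bad][1], fix[idx[1], "CHROM"], fix[idx[1], "POS"],
                   sample_ids[idx[2]]))
    }
    miss <- is.na(gt) | first == "." | second == "."
    val <- (first == "1") + (second == "1")
    val[miss] <- NA_integer_
    dos <- t(matrix(as.integer(val), nrow = p, ncol = n))
  } else {
    dos <- matrix(integer(0), nrow = n, ncol = p)
  }

  snp_ids <- if (p > 0) fix[, "ID"] else character(0)
  if (p > 0 && any(is.na(snp_ids) | snp_ids == ".")) {
    auto <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
    snp_ids <- ifelse(is.na(snp_ids) | snp_ids == ".", auto, snp_ids)
  }

  labels <- NULL
  if (!is.null(labels_path)) {
    lab_tab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                                 col.names = c("sample_id", "class"),
                                 colClasses = "character")
    missing_samples <- setdiff(sample_ids, lab_tab$sample_id)
    if (length(missing_samples) > 0) {
      stop("samples missing from label table: ",
           paste(missing_samples, collapse = ", "))
    }
    labels <- lab_tab$class[match(sample_ids, lab_tab$sample_id)]
  }

  ds <- genotype_dataset(
    dosages = dos, snp_ids = snp_ids,
    chrom = if (p > 0) fix[, "CHROM"] else character(0),
    pos = if (p > 0) as.integer(fix[, "POS"]) else integer(0),
    sample_ids = sample_ids, labels = labels)
  attr(ds, "n_multiallelic_dropped") <- n_multi
  ds
}

#' Write a genotype dataset to a VCF file
#'
#' Minimal VCF 4.2 text output with a GT-only FORMAT column; dosage 0/1/2 is
#' written as 0/0, 0/1, 1/1 and `NA` as "./.". Round-trips exactly through
#' [read_vcf()].
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @param labels_path Optional path for a companion 2-column labels TSV.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path, labels_path = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ds$sample_ids), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  p <- ncol(ds$dosages)
  body <- character(p)
  for (j in seq_len(p)) {
    d <- ds$dosages[, j]
    g <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    body[j] <- paste(c(ds$chrom[j], ds$pos[j], ds$snp_ids[j], "A", "G", ".",
                       "PASS", ".", "GT", g), collapse = "\t")
  }
  writeLines(c(header, body), path)
  if (!is.null(labels_path)) {
    if (is.null(ds$labels)) stop("dataset has no labels to write")
    utils::write.table(
      data.frame(sample_id = ds$sample_ids, class = as.character(ds$labels)),
      labels_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export the dosage matrix as whitespace-delimited text
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path; first row holds SNP ids, first column sample ids.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(ds, path) {
  utils::write.table(ds$dosages, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Apply quality-control filters to a genotype dataset
#'
#' Removes multiallelic SNPs (when flagged), SNPs with call rate below
#' `call_rate_min` and SNPs with minor allele frequency below `maf_min`
#' (MAF computed from non-missing dosages only). Genotypes still missing in
#' the retained SNPs are imputed to the per-SNP mode unless
#' `impute = "error"`.
#'
#' @param ds A [genotype_dataset()].
#' @param cfg A [qc_config()].
#' @param impute `"mode"` (default) or `"error"` (refuse residual missing).
#' @return A filtered `genotype_dataset` whose `qc_removed` attribute records
#'   the number of SNPs removed by each filter.
#' @export
apply_qc <- function(ds, cfg = qc_config(), impute = c("mode", "error")) {
  impute <- match.arg(impute)
  dos <- ds$dosages
  n <- nrow(dos)
  call_rate <- colMeans(!is.na(dos))
  alt_freq <- colMeans(dos, na.rm = TRUE) / 2
  alt_freq[is.nan(alt_freq)] <- 0
  maf <- pmin(alt_freq, 1 - alt_freq)
  rm_multi <- if (cfg$biallelic_only) ds$multiallelic else rep(FALSE, ncol(dos))
  rm_cr <- !rm_multi & call_rate < cfg$call_rate_min
  rm_maf <- !rm_multi & !rm_cr & maf < cfg$maf_min
  keep <- !(rm_multi | rm_cr | rm_maf)
  if (!any(keep)) stop("empty dataset after QC")
  out <- subset_dataset(ds, snps = which(keep))
  if (anyNA(out$dosages)) {
    if (impute == "error") stop("missing genotypes remain after QC")
    for (j in which(colSums(is.na(out$dosages)) > 0)) {
      d <- out$dosages[, j]
      tab <- tabulate(d + 1L, nbins = 3L)
      out$dosages[is.na(d), j] <- which.max(tab) - 1L
    }
  }
  attr(out, "qc_removed") <- c(multiallelic = sum(rm_multi),
                               call_rate = sum(rm_cr), maf = sum(rm_maf))
  out
}

#' Stratified train/test split
#'
#' Splits individuals so that each class contributes `round(test_fraction *
#' class size)` individuals to the test set (within one individual of the
#' exact proportion), mirroring a breed-balanced train/test design.
#' Deterministic given `seed`.
#'
#' @param ds A labeled [genotype_dataset()].
#' @param test_fraction Fraction of each class assigned to the test set.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (both `genotype_dataset`).
#' @export
split_train_test <- function(ds, test_fraction, seed) {
  if (is.null(ds$labels)) stop("labels required for a stratified split")
  stopifnot(test_fraction >= 0, test_fraction < 1)
  counts <- table(ds$labels)
  if (any(counts < 2)) {
    stop("class with fewer than 2 members: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in levels(ds$labels)) {
    members <- which(ds$labels == cl)
    n_test <- round(test_fraction * length(members))
    if (n_test > 0) test_idx <- c(test_idx, sample(members, n_test))
  }
  train_idx <- setdiff(seq_len(nrow(ds$dosages)), test_idx)
  list(train = subset_dataset(ds, samples = sort(train_idx)),
       test = subset_dataset(ds, samples = sort(test_idx)))
}

#' SNP reduction rate of a feature selection
#'
#' Percentage of the initial SNP panel discarded by a selection step,
#' `100 * (1 - kept / initial)`.
#'
#' @param n_initial Number of SNPs before selection.
#' @param n_selected Number of SNPs retained.
#' @return Percentage in [0, 100].
#' @export
reduction_rate <- function(n_initial, n_selected) {
  stopifnot(n_initial > 0, n_selected >= 0, n_selected <= n_initial)
  100 * (1 - n_selected / n_initial)
}
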