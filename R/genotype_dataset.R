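#' Construct a genotype dataset
#'
#' The universal container for all selection and classification steps: an
#' N x P matrix of ALT-allele dosages (0/1/2; `NA` marks a missing genotype
#' before quality control), SNP coordinates and optional class labels.
#'
#' @param dosages Integer matrix, individuals in rows, SNPs in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param snp_ids Character vector of P SNP identifiers (unique).
#' @param chrom Character vector of P chromosome labels.
#' @param pos Integer vector of P base-pair positions (1-based, strictly
#'   increasing within each chromosome).
#' @param sample_ids Character vector of N sample identifiers (unique).
#' @param labels Optional factor/character vector of N class labels.
#' @param multiallelic Optional logical vector of P flags marking SNPs whose
#'   source record carried more than one ALT allele (such SNPs are removed
#'   by [apply_qc()] when `biallelic_only` is set).
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, snp_ids, chrom, pos, sample_ids,
                             labels = NULL, multiallelic = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  p <- ncol(dosages)
  n <- nrow(dosages)
  snp_ids <- as.character(snp_ids)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  sample_ids <- as.character(sample_ids)
  stopifnot(length(snp_ids) == p, length(chrom) == p, length(pos) == p,
            length(sample_ids) == n)
  if (anyDuplicated(snp_ids)) stop("duplicated snp_ids")
  if (anyDuplicated(sample_ids)) stop("duplicated sample_ids")
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    pc <- pos[chrom == ch]
    if (length(pc) > 1 && any(diff(pc) <= 0)) {
      stop("pos must be strictly increasing within chromosome ", ch)
    }
  }
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, p)
  stopifnot(length(multiallelic) == p)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    labels <- factor(as.character(labels))
    if (n >= 2 && nlevels(labels) < 2) {
      stop("labels must cover at least 2 classes")
    }
  }
  dimnames(dosages) <- list(sample_ids, snp_ids)
  structure(
    list(dosages = dosages, snp_ids = snp_ids, chrom = chrom, pos = pos,
         sample_ids = sample_ids, labels = labels,
         multiallelic = as.logical(multiallelic)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom), collapse = ", ")))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  } else cat("  classes: (none)\n")
  nm <- sum(is.na(x$dosages))
  if (nm > 0) cat(sprintf("  missing genotypes: %d\n", nm))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype dataset
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_individuals <- function(ds) nrow(ds$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(ds) ncol(ds$dosages)

#' Subset a genotype dataset
#'
#' @param ds A `genotype_dataset`.
#' @param samples Optional index/logical/character vector of individuals.
#' @param snps Optional index/logical/character vector of SNPs.
#' @return A new `genotype_dataset`. SNP subsets must preserve position order
#'   within chromosomes.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(ds$dosages))
  if (is.null(snps)) snps <- seq_len(ncol(ds$dosages))
  if (is.character(samples)) samples <- match(samples, ds$sample_ids)
  if (is.character(snps)) snps <- match(snps, ds$snp_ids)
  if (anyNA(samples) || anyNA(snps)) stop("unknown sample or SNP identifier")
  genotype_dataset(
    dosages = ds$dosages[samples, snps, drop = FALSE],
    snp_ids = ds$snp_ids[snps], chrom = ds$chrom[snps], pos = ds$pos[snps],
    sample_ids = ds$sample_ids[samples],
    labels = if (!is.null(ds$labels)) droplevels(ds$labels[samples]),
    multiallelic = ds$multiallelic[snps])
}
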