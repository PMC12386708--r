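#' TagSNP selection configuration
#'
#' @param window_bp Comparison horizon in base pairs (default 100,000): only
#'   SNPs within this distance can prune each other.
#' @param step_bp Retained as a knob for windowed variants (default 1,000);
#'   the greedy scan itself is step-free.
#' @param r2_max Maximum tolerated squared genotype correlation between a
#'   candidate and any retained tag (default 0.5).
#' @return A `tag_config` list.
#' @export
tag_config <- function(window_bp = 100000L, step_bp = 1000L, r2_max = 0.5) {
  stopifnot(window_bp >= 1, step_bp >= 1, step_bp <= window_bp,
            r2_max >= 0, r2_max <= 1)
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp), r2_max = r2_max),
            class = "tag_config")
}

#' Squared genotype correlation between two SNPs
#'
#' Composite linkage disequilibrium: the squared Pearson correlation of the
#' two dosage vectors (works on unphased data). Returns 0 when either vector
#' is constant.
#'
#' @param g1,g2 Equal-length dosage vectors (length >= 2).
#' @return R-squared in [0, 1].
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  if (length(g1) < 2) stop("need at least 2 individuals")
  if (stats::var(g1) == 0 || stats::var(g2) == 0) return(0)
  stats::cor(g1, g2)^2
}

#' Greedy tagSNP selection within bounded genomic windows
#'
#' Scans each chromosome in position order. A SNP is retained as a tag if
#' and only if its squared correlation with every already-retained tag
#' within `window_bp` upstream is at most `r2_max`; otherwise it is pruned
#' and the pruning tag and R-squared are recorded in the manifest. The
#' result is inclusion-maximal: every pruned SNP exceeds `r2_max` with at
#' least one retained in-window tag.
#'
#' @param ds A QC'd [genotype_dataset()] with positions sorted within
#'   chromosomes.
#' @param cfg A [tag_config()].
#' @return A [feature_selection_result()] with method `"tagging"`; its
#'   diagnostics hold the pruning `manifest` data frame
#'   (pruned_id, tag_id, r2).
#' @export
select_tag_snps <- function(ds, cfg = tag_config()) {
  dos <- ds$dosages
  storage.mode(dos) <- "double"
  p <- ncol(dos)
  keep <- logical(p)
  pruned_by <- integer(p)
  pruned_r2 <- numeric(p)
  n_mono <- 0L
  for (ch in unique(ds$chrom)) {
    idx <- which(ds$chrom == ch)
    if (any(diff(ds$pos[idx]) <= 0)) {
      stop("positions not sorted within chromosome ", ch)
    }
    tags <- integer(0)
    for (j in idx) {
      in_window <- tags[ds$pos[tags] >= ds$pos[j] - cfg$window_bp]
      if (stats::var(dos[, j]) == 0) {
        # monomorphic: r2 = 0 with everything, always retained
        n_mono <- n_mono + 1L
        keep[j] <- TRUE
        tags <- c(tags, j)
        next
      }
      worst <- 0
      worst_tag <- NA_integer_
      if (length(in_window) > 0) {
        r2 <- suppressWarnings(
          as.numeric(stats::cor(dos[, j], dos[, in_window, drop = FALSE]))^2)
        r2[is.na(r2)] <- 0   # monomorphic tags
        w <- which.max(r2)
        worst <- r2[w]
        worst_tag <- in_window[w]
      }
      if (worst > cfg$r2_max) {
        pruned_by[j] <- worst_tag
        pruned_r2[j] <- worst
      } else {
        keep[j] <- TRUE
        tags <- c(tags, j)
      }
    }
  }
  assign <- factor(ifelse(keep, "relevant", "irrelevant"),
                   levels = c("relevant", "irrelevant"))
  names(assign) <- ds$snp_ids
  pruned <- which(!keep)
  manifest <- data.frame(pruned_id = ds$snp_ids[pruned],
                         tag_id = ds$snp_ids[pruned_by[pruned]],
                         r2 = pruned_r2[pruned],
                         stringsAsFactors = FALSE)
  feature_selection_result(
    relevant_ids = ds$snp_ids[keep],
    cluster_assignments = assign,
    centroids = matrix(numeric(0), 0, 0), method = "tagging",
    diagnostics = list(manifest = manifest, n_monomorphic = n_mono,
                       config = cfg))
}
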