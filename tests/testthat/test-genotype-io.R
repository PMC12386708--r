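test_that("GT fields parse to ALT-allele dosages, phased or unphased", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1",
    "1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t./.\t1|0\t0/1",
    "1\t300\tsnpC\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2"), vcf)
  ds <- read_vcf(vcf)
  expect_equal(dim(ds$dosages), c(3L, 2L))   # multiallelic record dropped
  expect_equal(attr(ds, "n_multiallelic_dropped"), 1L)
  expect_equal(unname(ds$dosages[, "snpA"]), c(0L, 1L, 2L))
  expect_equal(unname(ds$dosages[, "snpB"]), c(NA_integer_, 1L, 1L))
})

test_that("empty VCF body gives P = 0 with the header's sample count", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc"), vcf)
  ds <- suppressWarnings(read_vcf(vcf))
  expect_equal(n_snps(ds), 0L)
  expect_equal(n_individuals(ds), 3L)
})

test_that("malformed GT errors name the record; missing labels are listed", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\tx/y"), vcf)
  expect_error(read_vcf(vcf), "malformed GT.*1:100", )
  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1"), vcf2)
  lab <- tempfile()
  writeLines("a\tclassX", lab)
  expect_error(read_vcf(vcf2, lab), "missing from label table: b")
})

test_that("write_vcf / read_vcf round-trips dosages, ids and labels", {
  sim <- simulate_dataset(sim_config(n_per_class = c(3, 3), p_snps = 2,
                                     n_signal = 0, seed = 5))
  ds <- sim$dataset
  vcf <- tempfile(fileext = ".vcf")
  lab <- tempfile()
  write_vcf(ds, vcf, lab)
  rt <- read_vcf(vcf, lab)
  expect_identical(rt$dosages, ds$dosages)
  expect_identical(rt$pos, ds$pos)
  expect_identical(rt$snp_ids, ds$snp_ids)
  expect_identical(as.character(rt$labels), as.character(ds$labels))
})

test_that("QC removes multiallelic, low-MAF and low-call-rate SNPs by hand count", {
  n <- 10
  clean1 <- c(rep(0L, 3), rep(1L, 4), rep(2L, 3))
  clean2 <- c(rep(2L, 5), rep(1L, 3), rep(0L, 2))
  low_maf <- c(1L, rep(0L, 9))             # MAF 0.05 exactly -> retained
  too_low_maf <- c(rep(0L, 10))            # MAF 0 -> removed
  low_cr <- clean1; low_cr[1] <- NA        # call rate 0.9 -> removed
  multi <- clean2
  ds <- toy_dataset(list(clean1, multi, too_low_maf, low_cr, low_maf, clean2),
                    multiallelic = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  out <- apply_qc(ds)
  expect_setequal(out$snp_ids, c("s01", "s05", "s06"))
  expect_equal(attr(out, "qc_removed"),
               c(multiallelic = 1L, call_rate = 1L, maf = 1L))
})

test_that("QC keeps a SNP at MAF exactly 0.05 and is idempotent", {
  maf05 <- c(1L, rep(0L, 9))
  ds <- toy_dataset(list(maf05, c(rep(0L, 5), rep(1L, 3), 2L, 2L)))
  out <- apply_qc(ds)
  expect_true("s01" %in% out$snp_ids)
  out2 <- apply_qc(out)
  expect_identical(out2$dosages, out$dosages)
  expect_equal(unname(attr(out2, "qc_removed")), c(0L, 0L, 0L))
})

test_that("QC mode-imputes residual missing genotypes and can refuse to", {
  g <- c(0L, 0L, 0L, 1L, 2L, 2L, 1L, 0L, 0L, NA)   # call rate 0.9 < 0.95
  clean <- c(rep(0L, 5), rep(1L, 5))
  ds <- toy_dataset(list(g, clean))
  out <- apply_qc(ds, qc_config(call_rate_min = 0.85))
  expect_false(anyNA(out$dosages))
  expect_equal(unname(out$dosages[10, "s01"]), 0L)  # mode of observed
  expect_error(apply_qc(ds, qc_config(call_rate_min = 0.85), impute = "error"),
               "missing genotypes remain")
})

test_that("QC on an all-bad panel errors", {
  ds <- toy_dataset(list(rep(0L, 10)))
  expect_error(apply_qc(ds), "empty dataset after QC")
})

test_that("stratified split hits per-class counts and partitions the samples", {
  sim <- simulate_dataset(sim_config(n_per_class = rep(20, 5), p_snps = 30,
                                     n_signal = 0, seed = 2))
  ds <- sim$dataset
  sp <- split_train_test(ds, test_fraction = 0.2, seed = 7)
  expect_equal(as.integer(table(sp$test$labels)), rep(4L, 5))
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), ds$sample_ids)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  sp2 <- split_train_test(ds, test_fraction = 0.2, seed = 7)
  expect_identical(sp2$test$sample_ids, sp$test$sample_ids)

  sp0 <- split_train_test(ds, test_fraction = 0, seed = 7)
  expect_equal(n_individuals(sp0$train), n_individuals(ds))
  expect_equal(n_individuals(sp0$test), 0L)
})

test_that("a 1825-individual five-class panel splits 1460/365 with matched proportions", {
  counts <- c(490, 450, 400, 300, 185)   # five classes, N = 1825
  labels <- rep(sprintf("breed%d", 1:5), counts)
  dos <- matrix(sample(0:2, 1825 * 3, replace = TRUE), nrow = 1825)
  ds <- genotype_dataset(dos, snp_ids = c("a", "b", "c"),
                         chrom = rep("1", 3), pos = c(100L, 200L, 300L),
                         sample_ids = sprintf("ind%04d", 1:1825),
                         labels = labels)
  sp <- split_train_test(ds, test_fraction = 0.2, seed = 3)
  expect_equal(n_individuals(sp$train), 1460L)
  expect_equal(n_individuals(sp$test), 365L)
  prop_train <- prop.table(table(sp$train$labels))
  prop_test <- prop.table(table(sp$test$labels))
  expect_true(all(abs(prop_train - prop_test) < 0.005))
})

test_that("split refuses a singleton class, naming it", {
  dos <- matrix(sample(0:2, 5 * 2, replace = TRUE), nrow = 5)
  ds <- genotype_dataset(dos, snp_ids = c("a", "b"), chrom = rep("1", 2),
                         pos = c(1L, 2L), sample_ids = sprintf("i%d", 1:5),
                         labels = c("x", "x", "x", "x", "lonely"))
  expect_error(split_train_test(ds, 0.2, 1), "lonely")
})
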