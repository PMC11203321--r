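test_that("VCF parsing matches hand decoding of GT fields", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "1\t100\tm1\tA\tC\t.\t.\t.\tGT\t0/0\t1/1\t./.",
    "1\t200\tm2\tG\tT\t.\t.\t.\tGT\t1/1\t0/0\t0/0",
    "1\t300\tm3\tA\tG,T\t.\t.\t.\tGT\t0/0\t1/1\t2/2",
    "2\t150\tm4\tC\tA\t.\t.\t.\tGT\t1/1\t1/1\t0/0",
    "2\t250\tm5\tT\tTA\t.\t.\t.\tGT\t0/0\t0/0\t1/1"), tf)
  g <- read_genotypes(tf)
  # multi-allelic m3 and indel m5 dropped; dosage decoded by hand
  expect_equal(dim(g), c(3, 3))
  expect_equal(unname(g$dosage[, "m1"]), c(0, 2, NA))
  expect_equal(unname(g$dosage[, "m2"]), c(2, 0, 0))
  expect_equal(unname(g$dosage[, "m4"]), c(2, 2, 0))
  expect_equal(attr(g, "n_multiallelic_dropped"), 1)
  expect_equal(attr(g, "n_nonsnp_dropped"), 1)

  bad <- tempfile(fileext = ".vcf")
  writeLines("not a vcf", bad)
  expect_error(read_genotypes(bad), class = "flowerGS_format_error")
})

test_that("an empty variant section yields a 0-marker matrix", {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t")), tf)
  g <- read_genotypes(tf)
  expect_equal(dim(g), c(2, 0))
})

test_that("VCF and HapMap round-trips preserve dosages and the map", {
  fx <- small_panel()
  g <- inject_missingness(fx$pop$geno[1:10, 1:40], 0.1, seed = 51)
  for (fmt in c("vcf", "hapmap")) {
    tf <- tempfile(fileext = if (fmt == "vcf") ".vcf" else ".hmp.txt")
    write_genotypes(g, tf, fmt)
    back <- read_genotypes(tf)
    expect_equal(unname(back$dosage), unname(g$dosage))
    expect_equal(back$map$pos, g$map$pos)
    expect_equal(as.character(back$map$chrom), as.character(g$map$chrom))
  }
  imp <- impute_mean(g)
  expect_error(write_genotypes(imp, tempfile(), "vcf"),
               class = "flowerGS_error")
})

test_that("marker filters apply strict thresholds in missing-then-MAF order", {
  # 10 lines x 10 markers engineered: 2 fail missing rate, 1 fails MAF
  d <- matrix(2, 10, 10)
  d[, 2] <- c(0, 0, 0, 0, 0, 2, 2, 2, 2, 2)            # MAF 0.5, keep
  d[1:2, 3] <- NA                                       # MR 0.2, remove
  d[1:3, 4] <- NA                                       # MR 0.3, remove
  d[1, 5] <- NA; d[2:4, 5] <- 0                         # MR 0.1, MAF 0.33, keep
  d[, 6] <- c(2, rep(0, 9))                             # MAF 0.1, keep
  d[, 1] <- c(0, 0, rep(2, 8))                          # MAF 0.2, keep
  d[, 7] <- 0                                           # MAF 0, remove
  d[, 8] <- c(0, 0, 0, 2, 2, 2, 0, 2, 2, 0)
  gm <- geno_matrix(d, data.frame(marker = paste0("1_", 1:10 * 10), chrom = 1,
                                  pos = 1:10 * 10))
  fl <- filter_markers(gm)
  expect_equal(fl$report$markers_in, 10)
  expect_equal(fl$report$removed_by_missing, 2)
  expect_equal(fl$report$removed_by_maf, 3)   # constant markers 9,10 + m7
  expect_equal(fl$report$markers_out, 5)
  expect_equal(fl$report$markers_out,
               fl$report$markers_in - fl$report$removed_by_missing -
                 fl$report$removed_by_maf)
  # filtering is idempotent
  fl2 <- filter_markers(fl$geno)
  expect_equal(fl2$report$removed_by_missing + fl2$report$removed_by_maf, 0)
})

test_that("boundary markers at exactly the thresholds are removed", {
  # MAF exactly 0.05: 1 alt allele among 20 -> removed (strict >)
  d <- matrix(0, 10, 3)
  d[1, 1] <- 2                                          # MAF 0.1 keep
  d[, 2] <- c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  d2 <- matrix(c(rep(NA, 2), rep(0, 8)), 10, 1)         # MR exactly 0.20
  d[, 3] <- c(0, 2, 2, 0, 0, 2, 0, 2, 0, 0)
  gm <- geno_matrix(cbind(d, d2),
                    data.frame(marker = paste0("1_", 1:4 * 10), chrom = 1,
                               pos = 1:4 * 10))
  # marker 2 has alt freq 0.1 -> MAF 0.1 keep; recode marker2 to exact 0.05:
  gm$dosage[1, 2] <- 1   # 1 alt allele / 20 = 0.05 -> removed
  fl <- filter_markers(gm)
  expect_false("1_20" %in% fl$geno$map$marker)   # MAF exactly 0.05 removed
  expect_false("1_40" %in% fl$geno$map$marker)   # MR exactly 0.20 removed
  expect_true("1_10" %in% fl$geno$map$marker)
  expect_true("1_30" %in% fl$geno$map$marker)
})

test_that("mean imputation fills missing calls with observed marker means", {
  gm <- geno_matrix(matrix(c(0, 2, NA, 2, 2, 2), 3, 2),
                    data.frame(marker = c("1_10", "1_20"), chrom = 1,
                               pos = c(10, 20)))
  imp <- impute_mean(gm)
  expect_equal(unname(imp$dosage[3, 1]), 1)
  expect_equal(unname(imp$dosage[, 2]), c(2, 2, 2))
  expect_equal(colMeans(imp$dosage),
               colMeans(gm$dosage, na.rm = TRUE))   # means preserved
  expect_identical(impute_mean(imp), imp)
  gm$dosage[, 2] <- NA
  expect_error(impute_mean(gm), class = "flowerGS_error")
})

test_that("PC covariates separate subpopulations and satisfy the spectral contracts", {
  set.seed(61)
  n <- 60; m <- 200
  lab <- rep(c(0, 1), each = n / 2)
  d <- 2 * matrix(rbinom(n * m, 1, ifelse(rep(lab, m) == 0, 0.2, 0.8)), n, m)
  gm <- geno_matrix(d, data.frame(marker = paste0("1_", seq_len(m) * 10),
                                  chrom = 1, pos = seq_len(m) * 10))
  pcs <- pca_covariates(gm, 3)
  expect_gte(abs(cor(pcs[, 1], lab)), 0.9)
  v <- apply(pcs, 2, var)
  expect_true(all(diff(v) <= 1e-8))                  # non-increasing
  cp <- crossprod(scale(pcs, scale = FALSE))
  off <- cp[upper.tri(cp)] / sqrt(diag(cp)[1] * diag(cp)[2])
  expect_true(all(abs(off) < 1e-8))                  # orthogonal scores
  # invariance (up to numerical noise) to marker permutation
  set.seed(62)
  perm <- sample(m)
  gm2 <- geno_matrix(d[, perm], gm$map)   # same markers, shuffled order
  pcs_perm <- pca_covariates(gm2, 3)
  expect_equal(abs(pcs_perm), abs(pcs), tolerance = 1e-8)
  expect_error(pca_covariates(gm, 100), class = "flowerGS_error")
})
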