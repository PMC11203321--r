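test_that("Bonferroni threshold arithmetic is exact", {
  thr <- bonferroni_threshold(134785, 0.05)
  expect_equal(signif(thr$p_threshold, 3), 3.71e-7)
  expect_equal(round(thr$neg_log10_threshold, 1), 6.4)
  expect_equal(bonferroni_threshold(1, 0.05)$p_threshold, 0.05)
  expect_error(bonferroni_threshold(0), class = "flowerGS_error")
  expect_error(bonferroni_threshold(10, 1.2), class = "flowerGS_error")
})

test_that("the inner scan reproduces a normal-equations regression oracle", {
  g <- toy_geno(20, 5, seed = 71)
  set.seed(72)
  cov <- cbind(rnorm(20), rnorm(20))
  y <- 0.5 * g$dosage[, 2] + cov[, 1] + rnorm(20)
  res <- single_marker_scan(g, y, covariates = cov)
  for (j in 1:5) {
    X <- cbind(1, cov, g$dosage[, j])
    # oracle: explicit normal-equations solve
    XtXi <- solve(crossprod(X))
    beta <- XtXi %*% crossprod(X, y)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (20 - ncol(X))
    tstat <- beta[4] / sqrt(s2 * XtXi[4, 4])
    p <- 2 * pt(-abs(tstat), 20 - ncol(X))
    expect_equal(res$effect[j], beta[4], tolerance = 1e-10)
    expect_equal(res$p_value[j], p, tolerance = 1e-10)
  }
})

test_that("a marker collinear with a covariate is flagged degenerate with p = 1", {
  g <- toy_geno(20, 5, seed = 73)
  set.seed(74)
  y <- rnorm(20)
  res <- single_marker_scan(g, y, covariates = g$dosage[, 3, drop = FALSE])
  expect_true(res$degenerate[3])
  expect_equal(res$p_value[3], 1)
})

test_that("null p-values from the inner scan are uniform", {
  # independent markers so the 500 p-values are approximately independent
  # (a Kolmogorov-Smirnov check on linked markers would test the LD
  # structure, not the scan's calibration)
  set.seed(899)
  d <- 2 * matrix(rbinom(200 * 500, 1, 0.5), 200, 500)
  g <- geno_matrix(d, data.frame(marker = paste0("1_", seq_len(500) * 10),
                                 chrom = 1, pos = seq_len(500) * 10))
  ok <- 0
  for (sd in 1:20) {
    set.seed(900 + sd)
    y <- rnorm(nrow(g$dosage))
    res <- single_marker_scan(g, y)
    ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
    ok <- ok + (ks$p.value > 0.01)
  }
  expect_gte(ok, 18)
})

test_that("multi-locus scans are deterministic and flag pseudo-QTNs consistently", {
  fx <- small_panel()
  bl <- small_blups()
  y <- setNames(bl$DTT, bl$line)
  pcs <- pca_covariates(fx$pop$geno, 3)
  r1 <- farmcpu_like_scan(fx$pop$geno, y, gwas_config("farmcpu_like"), pcs, "DTT")
  r2 <- farmcpu_like_scan(fx$pop$geno, y, gwas_config("farmcpu_like"), pcs, "DTT")
  expect_identical(r1, r2)
  b1 <- blink_like_scan(fx$pop$geno, y, gwas_config("blink_like"), pcs, "DTT")
  expect_identical(b1, blink_like_scan(fx$pop$geno, y,
                                       gwas_config("blink_like"), pcs, "DTT"))
  thr <- attr(r1, "p_threshold")
  expect_identical(r1$significant, r1$p_value < thr)
  expect_identical(b1$significant, b1$p_value < thr)
})

test_that("perfect-LD duplicates collapse to one pseudo-QTN in the LD-pruned scan", {
  fx <- small_panel()
  pop <- fx$pop
  d <- pop$geno$dosage[, 1:300]
  d[, 2] <- d[, 1]                       # duplicate marker in perfect LD
  map <- pop$geno$map[1:300, ]
  g <- geno_matrix(d, map)
  set.seed(81)
  y <- d[, 1] * 0.8 + rnorm(nrow(d), 0, 1)
  names(y) <- rownames(d)
  res <- blink_like_scan(g, y, gwas_config("blink_like"))
  pair <- res$pseudo_qtn[1:2]
  expect_equal(sum(pair), 1)
})

test_that("two planted QTLs in distinct bins are both reported as pseudo-QTNs", {
  fx <- small_panel()
  g <- fx$pop$geno
  fr <- colMeans(g$dosage) / 2
  common <- which(pmin(fr, 1 - fr) > 0.35)
  q1 <- common[min(which(g$map$chrom[common] == 1))]   # chromosome 1
  q2 <- common[min(which(g$map$chrom[common] == 3))]   # chromosome 3
  z1 <- g$dosage[, q1] - mean(g$dosage[, q1])
  z2 <- g$dosage[, q2] - mean(g$dosage[, q2])
  set.seed(82)
  y <- z1 * sqrt(0.15 / 0.7 / var(z1)) + z2 * sqrt(0.15 / 0.7 / var(z2)) +
    rnorm(nrow(g$dosage))
  names(y) <- rownames(g$dosage)
  res <- farmcpu_like_scan(g, y, gwas_config("farmcpu_like"))
  qtn <- res$marker[res$pseudo_qtn]
  expect_true(all(g$map$marker[c(q1, q2)] %in% qtn))
})

test_that("per-SNP PVE matches a brute-force nested-RSS oracle", {
  g <- toy_geno(30, 6, seed = 83)
  set.seed(84)
  y <- 0.9 * g$dosage[, 1] + 0.5 * g$dosage[, 4] + rnorm(30, 0, 0.8)
  res <- single_marker_scan(g, y)
  mk <- g$map$marker[c(1, 4)]
  res <- snp_pve(g, y, res, markers = mk)
  rss <- function(X) sum(lm.fit(X, y)$residuals^2)
  G2 <- g$dosage[, c(1, 4)]
  full <- rss(cbind(1, G2))
  for (j in 1:2) {
    red <- rss(cbind(1, G2[, -j, drop = FALSE]))
    expect_equal(res$pve[match(mk[j], res$marker)], 1 - full / red,
                 tolerance = 1e-10)
  }
  # orthogonal marker explains nothing
  res0 <- snp_pve(g, y, res, markers = g$map$marker[6], type = "marginal")
  expect_lt(res0$pve[6], 0.15)
})

test_that("PVE saturates when a single marker generates the phenotype", {
  g <- toy_geno(30, 4, seed = 85)
  y <- 1.5 * g$dosage[, 2]
  res <- single_marker_scan(g, y)
  res <- snp_pve(g, y, res, markers = g$map$marker[2])
  expect_gte(res$pve[2], 0.999)
})

test_that("overlap summaries count unique SNPs and sum PVE by model and trait", {
  mk <- function(model, trait, chrom, pos, pve)
    data.frame(model = model, trait = trait, chrom = chrom, pos = pos,
               pve = pve, significant = TRUE)
  res <- list(mk("A", "t1", c(1, 2), c(10, 20), c(0.1, 0.2)),
              mk("A", "t2", 1, 10, 0.05),
              mk("B", "t1", c(2, 3), c(20, 30), c(0.15, 0.25)))
  ov <- overlap_summary(res)
  expect_equal(ov$per_model$n_unique_snps[ov$per_model$model == "A"], 2)
  expect_equal(ov$per_model$n_unique_snps[ov$per_model$model == "B"], 2)
  a_t1 <- ov$per_model_trait[ov$per_model_trait$model == "A" &
                               ov$per_model_trait$trait == "t1", ]
  expect_equal(a_t1$total_pve, 0.3)
  expect_equal(ov$pleiotropic$snp, "1_10")
  expect_equal(unname(ov$venn["A&B"]), 1)
  # an empty entry does not crash the summary
  empty <- mk("C", "t1", 1, 99, 0.1)[0, ]
  ov2 <- overlap_summary(list(res[[1]], empty))
  expect_equal(sum(ov2$per_model$n_unique_snps), 2)
})

test_that("manhattan and qq tables carry the scan's -log10 p-values", {
  g <- toy_geno(20, 5, seed = 86)
  set.seed(87)
  res <- single_marker_scan(g, rnorm(20))
  tabs <- gwas_tables(res)
  expect_equal(tabs$manhattan$neg_log10_p, -log10(res$p_value))
  expect_equal(nrow(tabs$qq), 5)
  expect_true(all(diff(tabs$qq$observed) <= 0))
})
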