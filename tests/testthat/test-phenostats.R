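make_book <- function(values, env = "E1") {
  data.frame(line = sprintf("L%02d", seq_along(values)), env = env,
             rep = 1, trait = "T1", value = values)
}

test_that("descriptive statistics match hand moment arithmetic", {
  ds <- descriptive_stats(make_book(c(60, 60, 60)), combined = FALSE)
  expect_equal(ds$sd, 0)
  expect_equal(ds$cv_percent, 0)
  expect_equal(c(ds$min, ds$max), c(60, 60))

  ds <- descriptive_stats(make_book(c(58, 60, 62)), combined = FALSE)
  expect_equal(ds$skewness, 0, tolerance = 1e-12)

  x <- c(50, 55, 60, 65, 70)
  ds <- descriptive_stats(make_book(x), combined = FALSE)
  # oracle: direct sample moments
  m2 <- mean((x - 60)^2); m3 <- mean((x - 60)^3); m4 <- mean((x - 60)^4)
  expect_equal(ds$mean, 60)
  expect_equal(ds$sd, sqrt(250 / 4), tolerance = 1e-12)        # 7.9057
  expect_equal(ds$cv_percent, 100 * sqrt(62.5) / 60, tolerance = 1e-12)
  expect_equal(ds$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(ds$kurtosis, m4 / m2^2 - 3, tolerance = 1e-12)

  expect_error(descriptive_stats(make_book(c(1, 2))),
               class = "flowerGS_missing_cell")
})

test_that("balanced variance components equal the expected-mean-squares oracle and REML", {
  book <- balanced_book(10, 3, 2, s2g = 8, s2ge = 3, s2e = 2, seed = 31)
  vc <- fit_variance_components(book, "T1")           # auto -> anova
  # oracle: mean squares from a standard two-way ANOVA fit
  a <- anova(lm(value ~ env + line + line:env,
                data = transform(book, line = factor(line), env = factor(env))))
  MS_G <- a["line", "Mean Sq"]; MS_GE <- a["env:line", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  expect_equal(vc$sigma2_e, MSE, tolerance = 1e-10)
  expect_equal(vc$sigma2_ge, (MS_GE - MSE) / 2, tolerance = 1e-10)
  expect_equal(vc$sigma2_g, (MS_G - MS_GE) / 6, tolerance = 1e-10)
  # independent REML route (lme4) agrees on balanced data with interior
  # estimates
  vr <- fit_variance_components(book, "T1", method = "reml")
  expect_equal(vr$sigma2_g, vc$sigma2_g, tolerance = 1e-4)
  expect_equal(vr$sigma2_ge, vc$sigma2_ge, tolerance = 1e-4)
  expect_equal(vr$sigma2_e, vc$sigma2_e, tolerance = 1e-4)
})

test_that("REML handles unbalanced data and single-environment errors", {
  book <- balanced_book(12, 3, 2, 8, 3, 2, seed = 32)
  book <- book[-c(1, 5, 20, 40), ]                    # unbalance it
  vc <- fit_variance_components(book, "T1")
  expect_identical(vc$method, "reml")
  expect_true(all(coef(vc) >= 0))
  single <- balanced_book(10, 1, 2, 8, 0, 2, seed = 33)
  expect_error(fit_variance_components(single, "T1"),
               class = "flowerGS_gxe_inestimable")
})

test_that("noise-free data give zero interaction and error components", {
  book <- balanced_book(10, 3, 2, s2g = 8, s2ge = 0, s2e = 0, seed = 34)
  vc <- fit_variance_components(book, "T1")
  expect_equal(vc$sigma2_ge, 0, tolerance = 1e-10)
  expect_equal(vc$sigma2_e, 0, tolerance = 1e-10)
  lm_ <- tapply(book$value, book$line, mean)
  expect_equal(vc$sigma2_g, var(as.vector(lm_)), tolerance = 1e-8)
  expect_equal(vc$H2, 1)
})

test_that("entry-mean heritability reproduces the published worked examples", {
  expect_equal(round(100 * heritability_entry_mean(13.61, 9.22, 4.26, 4, 2), 2),
               82.75)
  expect_equal(round(100 * heritability_entry_mean(19.84, 10.68, 4.29, 4, 2), 2),
               86.09)
  expect_equal(heritability_entry_mean(5, 0, 0, E = 3, R = 4), 1)
  expect_error(heritability_entry_mean(0, 0, 0, E = 2, R = 2),
               class = "flowerGS_error")
})

test_that("heritability recovery on synthetic panels stays within 0.05", {
  # published-proportioned components, balanced 300-line trials
  errs <- vapply(1:6, function(sd) {
    f <- simulate_founders(12, 400, 4, seed = 700 + sd)
    pop <- simulate_dh_population(f, 15, 20, seed = 710 + sd)
    arch <- trait_architecture(pop, traits = "DTT",
                               components = c(13.61, 9.22, 4.26),
                               n_qtl = 60, seed = 720 + sd)
    sim <- simulate_phenotypes(pop, arch, seed = 730 + sd)
    vc <- fit_variance_components(sim$book, "DTT")
    abs(vc$H2 - 0.8275)
  }, 0)
  expect_lt(mean(errs), 0.05)
})

test_that("BLUPs shrink line means and match a dense mixed-model-equation oracle", {
  # 3 lines x 2 environments x 1 replicate toy
  set.seed(41)
  book <- data.frame(line = rep(c("A", "B", "C"), each = 2),
                     env = rep(c("E1", "E2"), 3), rep = 1, trait = "T1",
                     value = c(55, 57, 60, 64, 66, 69))
  vc <- fit_variance_components(book, "T1")
  bl <- compute_blups(book, vc)
  # oracle: dense Henderson MME at the same components
  X <- cbind(1, c(1, -1, 1, -1, 1, -1))          # intercept + env contrast
  Z <- kronecker(diag(3), c(1, 1))
  s2res <- vc$sigma2_ge + vc$sigma2_e       # G-by-E confounded with error
  s2res <- max(s2res, 1e-10 * max(vc$sigma2_g, 1))
  lam <- s2res / vc$sigma2_g
  W <- cbind(X, Z)
  C <- crossprod(W) + diag(c(0, 0, rep(lam, 3)))
  sol <- solve(C, crossprod(W, book$value))
  expect_equal(bl$blup, sol[1] + sol[3:5], tolerance = 1e-8)
  # closed-form ridge shrinkage of line means toward the grand mean
  lmn <- tapply(book$value, book$line, mean)
  shrink <- vc$sigma2_g / (vc$sigma2_g + s2res / 2)
  expect_equal(bl$blup, unname(mean(book$value) + shrink * (as.vector(lmn) - mean(book$value))),
               tolerance = 1e-6)
  expect_lte(var(bl$blup), var(as.vector(lmn)))
})

test_that("BLUPs equal entry means in the no-noise limit", {
  book <- balanced_book(8, 3, 2, s2g = 10, s2ge = 0, s2e = 0, seed = 42)
  vc <- fit_variance_components(book, "T1")
  bl <- compute_blups(book, vc)
  lmn <- tapply(book$value, book$line, mean)
  # entry means corrected for (sum-to-zero) environment effects = raw means
  expect_equal(bl$blup, unname(as.vector(lmn)), tolerance = 1e-6)
})

test_that("BLUPs track true breeding values and shrink for every trait", {
  fx <- small_panel()
  bl <- small_blups()
  for (tr in fx$arch$traits) {
    tt <- fx$sim$truth[fx$sim$truth$trait == tr, ]
    expect_gte(cor(bl[[tr]], tt$tbv[match(bl$line, tt$line)]), 0.85)
    b <- fx$sim$book[fx$sim$book$trait == tr, ]
    lmn <- tapply(b$value, b$line, mean)
    expect_lte(var(bl[[tr]]), var(as.vector(lmn)))
    # high-heritability balanced data: BLUPs nearly collinear with means
    expect_gte(cor(bl[[tr]], as.vector(lmn)[match(bl$line, names(lmn))]), 0.99)
  }
})

test_that("trait correlations behave on identities and emulate the published band", {
  bl <- small_blups()
  tc <- trait_correlations(bl)
  expect_equal(unname(diag(tc$r)), rep(1, 3))
  expect_true(isSymmetric(tc$r))
  # strongly pleiotropic pair lands in the published high-correlation band
  expect_gte(tc$r["DTP", "DTS"], 0.88)
  expect_lte(tc$r["DTP", "DTS"], 0.99)
  m <- cbind(a = bl$DTT, b = -bl$DTT)
  expect_equal(trait_correlations(m)$r["a", "b"], -1)
  expect_error(trait_correlations(cbind(a = rep(1, 5), b = rnorm(5))),
               class = "flowerGS_undefined_correlation")
})
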