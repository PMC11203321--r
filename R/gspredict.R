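# RR-BLUP genomic selection and the cross-validation experiment grid.
#
# Model: y = 1 mu + Z u + eps with u ~ N(0, I sigma2_u) over the centered
# marker matrix Z, so y ~ N(1 mu, sigma2_u (K + lambda I)) with K = Z Z'
# and lambda = sigma2_e / sigma2_u. lambda is estimated by restricted
# maximum likelihood profiled through the eigendecomposition of the
# (intercept-projected) kernel, optimizing the profile restricted
# log-likelihood in log(lambda) on [-10, 10]. Marker effects follow as
# u_hat = Z' (K + lambda I)^{-1} (y - 1 mu_hat); the training GEBVs are
# algebraically identical to the GBLUP kernel solution at the same
# lambda.

.LOG_LAMBDA_RANGE <- c(-10, 10)

#' Fit an RR-BLUP genomic prediction model
#'
#' @param train_geno a complete [geno_matrix] (or numeric lines x markers
#'   matrix) of the training lines.
#' @param train_blups named numeric vector or (line, value) data.frame of
#'   the training response (typically across-environment BLUPs).
#' @param lambda optional fixed shrinkage ratio sigma2_e/sigma2_u; when
#'   NULL (default) it is estimated by profile REML.
#' @return Object of class `rrblup`: intercept `mu`, `marker_effects`,
#'   `marker_means` (centering vector), `lambda` (= sigma2_e/sigma2_u),
#'   `sigma2_u`, `sigma2_e`, fitted training GEBVs, and a
#'   `lambda_boundary` flag set when the REML optimum sits at the edge of
#'   the search range.
#' @examples
#' f <- simulate_founders(4, 60, n_chromosomes = 2, seed = 1)
#' pop <- simulate_dh_population(f, 3, 20, seed = 2)
#' y <- rowSums(pop$geno$dosage[, 1:3]) + rnorm(60)
#' fit <- fit_rrblup(pop$geno, setNames(y, rownames(pop$geno$dosage)))
#' @export
fit_rrblup <- function(train_geno, train_blups, lambda = NULL) {
  if (inherits(train_geno, "geno_matrix")) {
    X <- train_geno$dosage
    y <- .align_blups(train_geno, train_blups)
  } else {
    X <- as.matrix(train_geno)
    y <- as.numeric(train_blups)
  }
  if (anyNA(X)) .fail("genotypes must be complete (impute first)")
  n <- nrow(X)
  if (n < 10) .fail("need at least 10 training lines")
  if (ncol(X) < 1) .fail("need at least 1 marker")
  if (sd(y) == 0) .fail("zero phenotypic variance in training response")

  mns <- colMeans(X)
  Z <- sweep(X, 2, mns)
  K <- tcrossprod(Z)

  # project out the intercept, then eigendecompose the projected kernel;
  # the constant offset separates the intercept direction (eigenvalue 0)
  # from genuine null-space directions of K
  offs <- max(mean(diag(K)), 1)
  SK <- K + offs * (diag(n) - 1 / n)
  eg <- eigen(SK, symmetric = TRUE)
  theta <- pmax(eg$values[seq_len(n - 1)] - offs, 0)
  eta <- as.vector(crossprod(eg$vectors[, seq_len(n - 1), drop = FALSE],
                             y - mean(y)))
  nr <- n - 1L

  neg_restricted_ll <- function(loglam) {
    lam <- exp(loglam)
    d <- theta + lam
    0.5 * (nr * log(sum(eta^2 / d)) + sum(log(d)))
  }
  if (is.null(lambda)) {
    opt <- optimize(neg_restricted_ll, .LOG_LAMBDA_RANGE, tol = 1e-6)
    lambda <- exp(opt$minimum)
    boundary <- min(abs(opt$minimum - .LOG_LAMBDA_RANGE)) < 1e-3
  } else {
    if (lambda <= 0) .fail("`lambda` must be positive")
    boundary <- FALSE
  }

  sigma2_u <- sum(eta^2 / (theta + lambda)) / nr
  sigma2_e <- lambda * sigma2_u

  # GLS intercept and BLUP of marker effects at the estimated lambda
  Vi <- solve(K + lambda * diag(n))
  one <- rep(1, n)
  mu <- as.numeric(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  r <- Vi %*% (y - mu)
  u <- as.vector(crossprod(Z, r))
  gebv <- mu + as.vector(Z %*% u)

  structure(list(mu = mu, marker_effects = setNames(u, colnames(X)),
                 marker_means = setNames(mns, colnames(X)),
                 lambda = lambda, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 lambda_boundary = boundary, fitted = setNames(gebv, rownames(X)),
                 n_train = n),
            class = "rrblup")
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("RR-BLUP model: %d markers, %d training lines\n",
              length(x$marker_effects), x$n_train))
  cat(sprintf("  mu = %.3f  lambda = %.4g (sigma2_u = %.4g, sigma2_e = %.4g)%s\n",
              x$mu, x$lambda, x$sigma2_u, x$sigma2_e,
              if (x$lambda_boundary) "  [lambda at search boundary]" else ""))
  invisible(x)
}

#' @export
coef.rrblup <- function(object, ...) object$marker_effects

#' Predict genomic estimated breeding values
#'
#' GEBV = mu + (dosage - training marker means) . marker_effects.
#'
#' @param object a fitted `rrblup` model.
#' @param geno a [geno_matrix] (or matrix) containing all trained markers.
#' @param ... unused.
#' @return Named numeric vector of GEBVs.
#' @export
predict.rrblup <- function(object, geno, ...) {
  X <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  want <- names(object$marker_effects)
  if (!is.null(colnames(X))) {
    miss <- setdiff(want, colnames(X))
    if (length(miss))
      .fail(sprintf("prediction genotypes lack trained marker(s): %s",
                    paste(head(miss, 5), collapse = ", ")))
    X <- X[, want, drop = FALSE]
  } else if (ncol(X) != length(want)) {
    .fail("prediction genotypes do not match trained markers")
  }
  Z <- sweep(X, 2, object$marker_means)
  setNames(object$mu + as.vector(Z %*% object$marker_effects), rownames(X))
}

#' @export
fitted.rrblup <- function(object, ...) object$fitted

# fold assignment for one repetition
.kfold_ids <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

.gs_row <- function(trait, experiment, level, acc) {
  data.frame(trait = trait, experiment = experiment, level = level,
             mean = mean(acc), sd = sd(acc), n = length(acc),
             stringsAsFactors = FALSE)
}

#' k-fold cross-validated prediction accuracy
#'
#' For each repetition, a fresh random k-fold partition: the model is
#' fit on the training folds (lambda re-estimated within every training
#' partition) and accuracy is the Pearson correlation between predicted
#' GEBVs and observed BLUPs in the held-out fold. The reported mean and
#' sd are over all fold-level correlations across repetitions.
#'
#' @param geno a complete [geno_matrix].
#' @param blups per-line response (named vector or line/value
#'   data.frame).
#' @param k number of folds (default 5).
#' @param reps number of repetitions (default 100).
#' @param trait trait label for the output.
#' @param seed optional integer seed.
#' @return data.frame of class `gs_result` (trait, experiment, level,
#'   mean, sd, n); attribute `accuracies` keeps the fold-level values.
#' @export
cross_validate <- function(geno, blups, k = 5, reps = 100, trait = "trait",
                           seed = NULL) {
  k <- .check_count(k, "k", min = 2L)
  reps <- .check_count(reps, "reps")
  y <- .align_blups(geno, blups)
  n <- length(y)
  if (n < 5 * k) .fail("need at least 5 lines per fold")
  .set_seed(seed)
  acc <- numeric(0)
  for (r in seq_len(reps)) {
    fold <- .kfold_ids(n, k)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      if (length(test) < 3) .fail("fold with fewer than 3 lines")
      fit <- fit_rrblup(geno$dosage[-test, , drop = FALSE], y[-test])
      pred <- predict(fit, geno$dosage[test, , drop = FALSE])
      acc <- c(acc, cor(pred, y[test]))
    }
  }
  out <- .gs_row(trait, "kfold", sprintf("k=%d", k), acc)
  structure(out, class = c("gs_result", "data.frame"), accuracies = acc)
}

#' Prediction accuracy as a function of training-population size
#'
#' Per fraction and repetition, a fresh random split assigns the stated
#' fraction of lines to training and the rest to prediction; accuracy is
#' the held-out Pearson correlation.
#'
#' @inheritParams cross_validate
#' @param fractions training fractions (default 0.1..0.9 by 0.1).
#' @return A `gs_result` with one row per fraction.
#' @export
sweep_training_size <- function(geno, blups, fractions = seq(0.1, 0.9, 0.1),
                                reps = 100, trait = "trait", seed = NULL) {
  reps <- .check_count(reps, "reps")
  y <- .align_blups(geno, blups)
  n <- length(y)
  if (floor(min(fractions) * n) < 10)
    .fail("smallest fraction leaves fewer than 10 training lines")
  .set_seed(seed)
  rows <- list()
  for (fr in fractions) {
    acc <- numeric(reps)
    for (r in seq_len(reps)) {
      tr <- sample.int(n, floor(fr * n))
      fit <- fit_rrblup(geno$dosage[tr, , drop = FALSE], y[tr])
      pred <- predict(fit, geno$dosage[-tr, , drop = FALSE])
      acc[r] <- cor(pred, y[-tr])
    }
    rows[[length(rows) + 1L]] <- .gs_row(trait, "training_size", fr, acc)
  }
  structure(do.call(rbind, rows), class = c("gs_result", "data.frame"))
}

#' Prediction accuracy as a function of marker density
#'
#' Per repetition and density, a fresh uniform random marker subset of
#' the stated size is drawn and 5-fold cross-validated accuracy is
#' computed on that subset.
#'
#' @inheritParams cross_validate
#' @param densities marker-subset sizes.
#' @return A `gs_result` with one row per density.
#' @export
sweep_marker_density <- function(geno, blups,
                                 densities = c(10, 30, 50, 100, 300, 500,
                                               1000, 3000, 5000),
                                 reps = 100, k = 5, trait = "trait",
                                 seed = NULL) {
  reps <- .check_count(reps, "reps")
  y <- .align_blups(geno, blups)
  m <- ncol(geno$dosage)
  if (max(densities) > m)
    .fail(sprintf("density %d exceeds available markers (%d)",
                  max(densities), m))
  .set_seed(seed)
  n <- length(y)
  rows <- list()
  for (dn in densities) {
    acc <- numeric(0)
    for (r in seq_len(reps)) {
      sub <- sample.int(m, dn)
      fold <- .kfold_ids(n, k)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        fit <- fit_rrblup(geno$dosage[-test, sub, drop = FALSE], y[-test])
        pred <- predict(fit, geno$dosage[test, sub, drop = FALSE])
        acc <- c(acc, cor(pred, y[test]))
      }
    }
    rows[[length(rows) + 1L]] <- .gs_row(trait, "marker_density", dn, acc)
  }
  structure(do.call(rbind, rows), class = c("gs_result", "data.frame"))
}

#' Prediction accuracy using the top GWAS-ranked markers
#'
#' Markers are ordered by association p-value (ties broken by genomic
#' order) and, for each k in `ks`, genomic selection is restricted to the
#' k lowest-p markers, with 5-fold cross-validated accuracy. By default
#' the ranking is computed once on the full population, reproducing the
#' usual (optimistically biased) two-stage procedure; set
#' `refit_in_fold = TRUE` to re-rank by a single-marker scan inside each
#' training fold instead (leakage-free variant).
#'
#' @inheritParams cross_validate
#' @param gwas_result an `assoc_result` covering the genotype's markers
#'   (ignored when `refit_in_fold = TRUE`).
#' @param ks numbers of top markers to keep.
#' @param refit_in_fold recompute the ranking within each training fold.
#' @param covariates PC covariates for the in-fold scan.
#' @return A `gs_result` with one row per k.
#' @export
sweep_top_snps <- function(geno, blups, gwas_result = NULL,
                           ks = c(1, 3, 5, 10, 30, 50, 100, 300, 500),
                           reps = 100, k = 5, trait = "trait",
                           refit_in_fold = FALSE, covariates = NULL,
                           seed = NULL) {
  reps <- .check_count(reps, "reps")
  y <- .align_blups(geno, blups)
  m <- ncol(geno$dosage)
  if (max(ks) > m) .fail("k exceeds the number of ranked markers")
  if (!refit_in_fold) {
    if (is.null(gwas_result)) .fail("`gwas_result` required unless refit_in_fold")
    idx <- match(gwas_result$marker, geno$map$marker)
    if (anyNA(idx)) .fail("gwas_result does not cover the genotype's markers")
    ord <- idx[order(gwas_result$p_value, gwas_result$chrom, gwas_result$pos)]
  }
  .set_seed(seed)
  n <- length(y)
  rows <- list()
  for (kk in ks) {
    acc <- numeric(0)
    for (r in seq_len(reps)) {
      fold <- .kfold_ids(n, k)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        if (refit_in_fold) {
          sc <- single_marker_scan(geno[-test, ], y[-test],
                                   covariates = covariates[-test, , drop = FALSE])
          ord_f <- order(sc$p_value, sc$chrom, sc$pos)
          sub <- ord_f[seq_len(kk)]
        } else sub <- ord[seq_len(kk)]
        fit <- fit_rrblup(geno$dosage[-test, sub, drop = FALSE], y[-test])
        pred <- predict(fit, geno$dosage[test, sub, drop = FALSE])
        a <- suppressWarnings(cor(pred, y[test]))
        acc <- c(acc, if (is.na(a)) 0 else a)
      }
    }
    rows[[length(rows) + 1L]] <- .gs_row(trait, "top_snps", kk, acc)
  }
  structure(do.call(rbind, rows), class = c("gs_result", "data.frame"))
}

#' @export
print.gs_result <- function(x, digits = 3, ...) {
  cat("Genomic-selection accuracy (Pearson r, held-out lines):\n")
  print.data.frame(transform(x, mean = round(mean, digits),
                             sd = round(sd, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.gs_result <- function(x, ...) {
  lv <- suppressWarnings(as.numeric(x$level))
  if (anyNA(lv)) lv <- seq_len(nrow(x))
  plot(lv, x$mean, type = "b", pch = 19,
       xlab = x$experiment[1], ylab = "prediction accuracy (r)", ...)
  invisible(x)
}
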