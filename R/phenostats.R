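# Phenotype statistics: descriptive summaries, variance components for the
# two-way line x environment model, entry-mean broad-sense heritability,
# BLUPs, and trait correlations.

.check_book <- function(book) {
  need <- c("line", "env", "rep", "trait", "value")
  if (!is.data.frame(book) || !all(need %in% names(book)))
    .fail("phenotype book must be a data.frame with columns line, env, rep, trait, value")
  if (any(!is.finite(book$value))) .fail("phenotype values must be finite")
  book
}

.moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  c(n = n, min = min(x), max = max(x), mean = m, sd = sd(x),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,     # excess kurtosis
    cv_percent = if (m != 0) 100 * sd(x) / m else 0)
}

#' Descriptive statistics per trait and environment
#'
#' Summarises each trait within each environment and in a "Combined"
#' pseudo-environment computed on per-line entry means across all
#' environments. SD uses the n-1 denominator; skewness is m3/m2^1.5 and
#' kurtosis is excess kurtosis m4/m2^2 - 3 (sample central moments);
#' CV% = 100 * sd / mean.
#'
#' @param book long-format phenotype data.frame (line, env, rep, trait,
#'   value).
#' @param combined include the Combined row per trait (default TRUE).
#' @return data.frame of class `descriptive_stats` with one row per
#'   trait x environment.
#' @export
descriptive_stats <- function(book, combined = TRUE) {
  book <- .check_book(book)
  out <- list()
  for (tr in unique(book$trait)) {
    b <- book[book$trait == tr, ]
    for (ev in unique(b$env)) {
      x <- b$value[b$env == ev]
      if (length(x) < 3)
        .fail(sprintf("fewer than 3 observations in cell trait=%s env=%s", tr, ev),
              class = "missing_cell")
      out[[length(out) + 1L]] <- data.frame(trait = tr, env = ev,
                                            t(.moments(x)))
    }
    if (combined) {
      em <- tapply(b$value, b$line, mean)
      out[[length(out) + 1L]] <- data.frame(trait = tr, env = "Combined",
                                            t(.moments(as.vector(em))))
    }
  }
  structure(do.call(rbind, out), class = c("descriptive_stats", "data.frame"))
}

# balanced-design check: every line x env cell present with equal replicates
.is_balanced <- function(b) {
  tab <- table(b$line, b$env)
  all(tab == tab[1]) && tab[1] >= 1
}

# closed-form ANOVA expected-mean-squares estimators for balanced data
.anova_vc <- function(b) {
  E <- length(unique(b$env))
  Rr <- as.integer(table(b$line, b$env)[1])
  nl <- length(unique(b$line))
  cell <- tapply(b$value, list(b$line, b$env), mean)
  lm_ <- rowMeans(cell); em_ <- colMeans(cell); gm <- mean(cell)
  MS_G <- E * Rr * sum((lm_ - gm)^2) / (nl - 1)
  if (E > 1) {
    resid_cell <- sweep(sweep(cell, 1, lm_), 2, em_) + gm
    MS_GE <- Rr * sum(resid_cell^2) / ((nl - 1) * (E - 1))
  } else MS_GE <- NA_real_
  if (Rr > 1) {
    fit <- b$value - cell[cbind(match(b$line, rownames(cell)),
                                match(b$env, colnames(cell)))]
    MSE <- sum(fit^2) / (nl * E * (Rr - 1))
  } else MSE <- 0
  if (E > 1) {
    s2e <- MSE
    s2ge <- max((MS_GE - MSE) / Rr, 0)
    s2g <- max((MS_G - MS_GE) / (Rr * E), 0)
    truncated <- (MS_GE - MSE) / Rr < 0 || (MS_G - MS_GE) / (Rr * E) < 0
  } else {
    s2e <- MSE; s2ge <- 0
    s2g <- max((MS_G - MSE) / Rr, 0)
    truncated <- (MS_G - MSE) < 0
  }
  list(sigma2_g = s2g, sigma2_ge = s2ge, sigma2_e = s2e,
       E = E, R = Rr, truncated = truncated)
}

#' Estimate variance components for one trait
#'
#' Fits the two-way model y_ijk = mu + g_i + e_j + (ge)_ij + eps_ijk with
#' environment fixed and line and line-by-environment random. Balanced
#' data use the closed-form ANOVA expected-mean-squares solution
#' (sigma2_e = MSE, sigma2_ge = (MS_GE - MSE)/R, sigma2_g =
#' (MS_G - MS_GE)/(R E), truncated at 0); unbalanced data are fit by REML
#' via [lme4::lmer]. For balanced data with interior estimates the two
#' routes coincide.
#'
#' @param book long-format phenotype data.frame.
#' @param trait trait name to fit.
#' @param method "auto" (ANOVA when balanced, else REML), "anova", or
#'   "reml".
#' @return Object of class `varcomp`: sigma2_g, sigma2_ge, sigma2_e, E,
#'   R, H2 (entry-mean heritability), trait, method, truncated flag.
#' @export
fit_variance_components <- function(book, trait,
                                    method = c("auto", "anova", "reml")) {
  book <- .check_book(book)
  method <- match.arg(method)
  b <- book[book$trait == trait, ]
  if (nrow(b) == 0) .fail(sprintf("trait '%s' not found", trait))
  E <- length(unique(b$env))
  nl <- length(unique(b$line))
  if (E < 2) .fail("single environment: G-by-E variance is inestimable",
                   class = "gxe_inestimable")
  if (nl < 2) .fail("need at least 2 lines")
  balanced <- .is_balanced(b)
  if (method == "anova" && !balanced)
    .fail("ANOVA estimators require balanced data; use method = 'reml'")
  use_anova <- method == "anova" || (method == "auto" && balanced)

  if (use_anova) {
    est <- .anova_vc(b)
    if (est$truncated)
      warning("negative variance-component estimate truncated at 0")
    mth <- "anova"
  } else {
    fit <- lme4::lmer(value ~ env + (1 | line) + (1 | line:env), data = b,
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v)) v else 0
    }
    Rr <- max(1L, round(nrow(b) / (nl * E)))
    est <- list(sigma2_g = pick("line"), sigma2_ge = pick("line:env"),
                sigma2_e = pick("Residual"), E = E, R = Rr,
                truncated = any(c(pick("line"), pick("line:env")) < 1e-10))
    mth <- "reml"
  }
  H2 <- heritability_entry_mean(est$sigma2_g, est$sigma2_ge, est$sigma2_e,
                                E = est$E, R = est$R)
  structure(c(est, list(H2 = H2, trait = trait, method = mth, n_lines = nl)),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("Variance components for %s (%s, %d lines, E=%d, R=%d)\n",
              x$trait, x$method, x$n_lines, x$E, x$R))
  cat(sprintf("  sigma2_g = %.*g  sigma2_ge = %.*g  sigma2_e = %.*g\n",
              digits, x$sigma2_g, digits, x$sigma2_ge, digits, x$sigma2_e))
  cat(sprintf("  entry-mean H2 = %.2f%%\n", 100 * x$H2))
  invisible(x)
}

#' @export
coef.varcomp <- function(object, ...) {
  c(sigma2_g = object$sigma2_g, sigma2_ge = object$sigma2_ge,
    sigma2_e = object$sigma2_e)
}

#' Entry-mean broad-sense heritability
#'
#' H2 = sigma2_g / (sigma2_g + sigma2_ge/E + sigma2_e/(E R)): the
#' repeatability of a line's mean over E environments with R replicates
#' each.
#'
#' @param sigma2_g a `varcomp` object, or the genotypic variance.
#' @param sigma2_ge genotype-by-environment interaction variance.
#' @param sigma2_e residual (plot error) variance.
#' @param E number of environments.
#' @param R number of replicates per environment.
#' @return Heritability as a fraction in [0, 1] (multiply by 100 for
#'   percent).
#' @examples
#' heritability_entry_mean(13.61, 9.22, 4.26, E = 4, R = 2)  # ~0.8275
#' @export
heritability_entry_mean <- function(sigma2_g, sigma2_ge = NULL, sigma2_e = NULL,
                                    E = NULL, R = NULL) {
  if (inherits(sigma2_g, "varcomp")) {
    vc <- sigma2_g
    sigma2_ge <- vc$sigma2_ge; sigma2_e <- vc$sigma2_e
    E <- vc$E; R <- vc$R; sigma2_g <- vc$sigma2_g
  }
  E <- .check_count(E, "E"); R <- .check_count(R, "R")
  if (any(c(sigma2_g, sigma2_ge, sigma2_e) < 0))
    .fail("variance components must be non-negative")
  den <- sigma2_g + sigma2_ge / E + sigma2_e / (E * R)
  if (den <= 0) .fail("zero denominator: all variance components are zero")
  sigma2_g / den
}

#' Compute line BLUPs for one trait
#'
#' Solves Henderson's mixed-model equations for the two-way model at the
#' supplied variance components (environment fixed with sum-to-zero
#' contrasts, line and line-by-environment random) and returns the
#' shrunken line means mu_hat + g_hat_i.
#'
#' @param book long-format phenotype data.frame.
#' @param vc a `varcomp` object (as from [fit_variance_components]).
#' @return data.frame of class `blup_table` with columns line, blup, and
#'   attribute `trait`.
#' @export
compute_blups <- function(book, vc) {
  book <- .check_book(book)
  if (!inherits(vc, "varcomp")) .fail("`vc` must be a varcomp object")
  b <- book[book$trait == vc$trait, ]
  if (nrow(b) == 0) .fail(sprintf("trait '%s' not found", vc$trait))
  counts <- table(b$line)
  drop <- names(counts)[counts == 0]
  if (length(drop)) {
    warning(sprintf("excluding %d line(s) with no observations", length(drop)))
    b <- b[!b$line %in% drop, ]
  }
  b$line <- factor(b$line)
  b$env <- factor(b$env)
  lines <- levels(b$line)
  y <- b$value

  # with a single replicate per cell the G-by-E effect is confounded with
  # the plot residual: fold it into the residual instead of fitting it
  R_eff <- max(table(b$line, b$env))
  use_ge <- vc$sigma2_ge > 1e-12 && length(unique(b$env)) > 1 && R_eff > 1
  s2e <- vc$sigma2_e + if (use_ge) 0 else vc$sigma2_ge
  if (s2e <= 0) s2e <- 1e-10 * max(vc$sigma2_g + vc$sigma2_ge, 1)
  if (vc$sigma2_g <= 1e-12) {
    warning("sigma2_g ~ 0: BLUPs collapse to the grand mean")
    out <- data.frame(line = lines, blup = mean(y), stringsAsFactors = FALSE)
    return(structure(out, class = c("blup_table", "data.frame"), trait = vc$trait))
  }

  X <- if (nlevels(b$env) > 1) {
    stats::model.matrix(~ env, data = b,
                        contrasts.arg = list(env = "contr.sum"))
  } else matrix(1, nrow(b), 1)
  Z1 <- Matrix::sparse.model.matrix(~ 0 + line, data = b)
  if (use_ge) {
    b$ge <- interaction(b$line, b$env, drop = TRUE)
    Z2 <- Matrix::sparse.model.matrix(~ 0 + ge, data = b)
    Z <- cbind(Z1, Z2)
    lam <- c(rep(s2e / vc$sigma2_g, ncol(Z1)),
             rep(s2e / vc$sigma2_ge, ncol(Z2)))
  } else {
    Z <- Z1
    lam <- rep(s2e / vc$sigma2_g, ncol(Z1))
  }
  # floor on the ridge keeps the MME numerically nonsingular in the
  # noise-free limit (intercept vs line-indicator collinearity)
  lam <- pmax(lam, 1e-8 * nrow(b))
  W <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  C <- Matrix::crossprod(W) +
    Matrix::Diagonal(ncol(W), x = c(rep(0, ncol(X)), lam))
  sol <- Matrix::solve(C, Matrix::crossprod(W, y))
  mu_hat <- sol[1, 1]                       # intercept under contr.sum
  g_hat <- as.vector(sol[ncol(X) + seq_along(lines), 1])
  out <- data.frame(line = lines, blup = mu_hat + g_hat,
                    stringsAsFactors = FALSE)
  structure(out, class = c("blup_table", "data.frame"), trait = vc$trait)
}

#' BLUPs for all traits as one wide table
#'
#' Convenience wrapper: fits variance components and computes BLUPs per
#' trait, returning a wide line x trait table (the response used by the
#' GWAS and genomic-selection stages).
#'
#' @param book long-format phenotype data.frame.
#' @param traits traits to include (default: all in the book).
#' @param method passed to [fit_variance_components].
#' @return data.frame with column `line` and one numeric column per trait;
#'   attribute `varcomp` holds the fitted components.
#' @export
blup_table <- function(book, traits = NULL, method = "auto") {
  book <- .check_book(book)
  if (is.null(traits)) traits <- unique(book$trait)
  vcs <- lapply(traits, function(tr) fit_variance_components(book, tr, method))
  tabs <- lapply(vcs, function(vc) compute_blups(book, vc))
  out <- data.frame(line = tabs[[1]]$line, stringsAsFactors = FALSE)
  for (i in seq_along(traits)) {
    m <- match(out$line, tabs[[i]]$line)
    out[[traits[i]]] <- tabs[[i]]$blup[m]
  }
  attr(out, "varcomp") <- setNames(vcs, traits)
  out
}

#' Pearson correlations between trait BLUPs
#'
#' @param blups wide BLUP table (column `line` plus one numeric column per
#'   trait), or a numeric matrix with traits in columns.
#' @return Object of class `trait_cor`: list with `r` (correlation
#'   matrix), `p` (two-sided p-values from the t transform of r), `codes`
#'   (significance stars: *** 0.001, ** 0.01, * 0.05), and `n`.
#' @export
trait_correlations <- function(blups) {
  if (is.data.frame(blups)) {
    num <- vapply(blups, is.numeric, logical(1))
    M <- as.matrix(blups[, num & names(blups) != "rep", drop = FALSE])
  } else M <- as.matrix(blups)
  M <- M[complete.cases(M), , drop = FALSE]
  n <- nrow(M)
  if (n < 3) .fail("need at least 3 lines with BLUPs")
  if (any(apply(M, 2, sd) == 0))
    .fail("zero-variance trait: correlation undefined",
          class = "undefined_correlation")
  r <- cor(M)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  diag(p) <- NA
  codes <- matrix(cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", "")),
                  nrow(p), dimnames = dimnames(p))
  structure(list(r = r, p = p, codes = codes, n = n), class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Trait correlations (Pearson, n = %d lines)\n", x$n))
  m <- format(round(x$r, digits))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (i != j) m[i, j] <- paste0(m[i, j], x$codes[i, j])
  print(m, quote = FALSE)
  invisible(x)
}
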