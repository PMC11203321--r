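# Multi-locus GWAS: Bonferroni threshold, OLS inner scan, and two
# iterative pseudo-QTN conditioning scans.
#
# Both multi-locus scans share one skeleton: (1) scan every marker by OLS
# with the current pseudo-QTN set S (plus PC covariates) as fixed
# covariates; (2) form a candidate set from markers passing a relaxed
# p-value screen; (3) re-select S among the candidates by Bayesian
# information criterion (BIC); (4) iterate until S stabilizes. They differ
# only in step 2/3: the bin variant keeps the best marker per genomic bin
# and grows S greedily; the LD variant prunes candidates by pairwise
# allelic r^2 and picks the BIC-minimizing prefix of the p-ordered list.
# Final p-values come from the last conditioned scan; pseudo-QTNs receive
# their coefficient p-values from the final joint model. Genome-wide
# significance is always declared at the Bonferroni threshold
# alpha / n_markers.

#' Bonferroni genome-wide significance threshold
#'
#' @param n_markers number of tested markers.
#' @param alpha family-wise error level (default 0.05).
#' @return List with `p_threshold` (= alpha / n_markers) and
#'   `neg_log10_threshold`.
#' @examples
#' bonferroni_threshold(134785)  # p ~ 3.71e-7, -log10 ~ 6.4
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  n_markers <- .check_count(n_markers, "n_markers")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    .fail("`alpha` must be in (0, 1)")
  p <- alpha / n_markers
  list(p_threshold = p, neg_log10_threshold = -log10(p))
}

#' GWAS scan configuration
#'
#' @param model "farmcpu_like", "blink_like", or "single_marker".
#' @param alpha significance level for the Bonferroni threshold.
#' @param n_pcs number of PC covariates.
#' @param bin_size genomic bin width in bp for the bin-based candidate
#'   step (farmcpu_like).
#' @param ld_r2_max candidates in LD above this squared allelic
#'   correlation with an already-kept candidate are pruned (blink_like).
#' @param relax_factor candidate screen uses p < alpha/n_markers *
#'   relax_factor.
#' @param max_pseudo_qtns cap on the pseudo-QTN set size.
#' @param max_iterations cap on conditioning iterations.
#' @param ebic_gamma extended-BIC penalty weight for pseudo-QTN selection
#'   (0 recovers the ordinary BIC; default 1, the conservative choice for
#'   marker counts far exceeding the sample size).
#' @param pve_type "partial" or "marginal" R^2 for [snp_pve].
#' @return List of class `gwas_config`.
#' @export
gwas_config <- function(model = c("farmcpu_like", "blink_like", "single_marker"),
                        alpha = 0.05, n_pcs = 3, bin_size = 1e7,
                        ld_r2_max = 0.7, relax_factor = 100,
                        max_pseudo_qtns = 10, max_iterations = 10,
                        ebic_gamma = 1,
                        pve_type = c("partial", "marginal")) {
  model <- match.arg(model)
  if (alpha <= 0 || alpha >= 1) .fail("`alpha` must be in (0,1)")
  if (bin_size <= 0) .fail("`bin_size` must be positive")
  if (ld_r2_max <= 0 || ld_r2_max > 1) .fail("`ld_r2_max` must be in (0,1]")
  structure(list(model = model, alpha = alpha, n_pcs = n_pcs,
                 bin_size = bin_size, ld_r2_max = ld_r2_max,
                 relax_factor = relax_factor,
                 max_pseudo_qtns = max_pseudo_qtns,
                 max_iterations = max_iterations,
                 ebic_gamma = ebic_gamma,
                 pve_type = match.arg(pve_type)),
            class = "gwas_config")
}

# exact per-marker OLS via residualization (Frisch-Waugh): regress y and
# every marker on the covariates once, then each marker slope/t/p follows
# from the residual cross-products. C must include the intercept.
.ols_scan <- function(y, G, C) {
  n <- length(y)
  qr_C <- qr(C)
  rk <- qr_C$rank
  ry <- qr.resid(qr_C, y)
  rG <- qr.resid(qr_C, G)
  gg <- colSums(rG^2)
  gy <- colSums(rG * ry)
  df <- n - rk - 1L
  beta <- ifelse(gg > 1e-10, gy / gg, 0)
  rss <- pmax(sum(ry^2) - beta^2 * gg, 0)
  se2 <- rss / df / gg
  tval <- ifelse(gg > 1e-10 & se2 > 0, beta / sqrt(se2), 0)
  p <- 2 * pt(-abs(tval), df = df)
  degen <- gg <= 1e-10
  p[degen] <- 1
  beta[degen] <- NA_real_
  list(effect = beta, p = pmin(pmax(p, .Machine$double.xmin), 1),
       degenerate = degen)
}

.align_blups <- function(geno, blups) {
  if (is.data.frame(blups)) {
    num <- which(vapply(blups, is.numeric, logical(1)))[1]
    y <- blups[[num]]
    names(y) <- blups$line
    blups <- y
  }
  if (!is.null(names(blups))) {
    m <- match(rownames(geno$dosage), names(blups))
    if (anyNA(m)) .fail("BLUPs missing for some genotyped lines")
    blups <- blups[m]
  } else if (length(blups) != nrow(geno$dosage)) {
    .fail("BLUP vector length does not match line count")
  }
  as.numeric(blups)
}

.assoc_result <- function(geno, effect, p, degenerate, pseudo, model, trait,
                          alpha, converged = TRUE) {
  thr <- bonferroni_threshold(ncol(geno$dosage), alpha)
  out <- data.frame(marker = geno$map$marker, chrom = geno$map$chrom,
                    pos = geno$map$pos, effect = effect, p_value = p,
                    significant = p < thr$p_threshold,
                    pseudo_qtn = pseudo, degenerate = degenerate,
                    pve = NA_real_, model = model, trait = trait,
                    stringsAsFactors = FALSE)
  structure(out, class = c("assoc_result", "data.frame"),
            alpha = alpha, p_threshold = thr$p_threshold,
            n_markers = ncol(geno$dosage), converged = converged)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Association scan (%s) for %s: %d markers, %d significant at p < %.3g%s\n",
              x$model[1], x$trait[1], nrow(x), sum(x$significant),
              attr(x, "p_threshold"),
              if (isTRUE(attr(x, "converged"))) "" else " [not converged]"))
  sig <- x[x$significant, c("marker", "chrom", "pos", "effect", "p_value", "pve")]
  if (nrow(sig)) print.data.frame(sig[order(sig$p_value), ], row.names = FALSE)
  invisible(x)
}

#' Single-marker OLS association scan
#'
#' Per marker, fits BLUP ~ intercept + PCs (+ optional extra fixed-marker
#' covariates) + marker dosage by ordinary least squares; the two-sided
#' p-value comes from the marker coefficient's t statistic. Markers with
#' no residual variance after conditioning are flagged degenerate with
#' p = 1. This is also the inner scan of both multi-locus models.
#'
#' @param geno a complete [geno_matrix].
#' @param blups named numeric vector or two-column data.frame (line,
#'   value) of the per-line response.
#' @param covariates optional lines x k numeric matrix (e.g. PC scores
#'   from [pca_covariates]).
#' @param trait trait label carried into the result.
#' @param alpha Bonferroni level.
#' @return An `assoc_result` data.frame (marker, chrom, pos, effect,
#'   p_value, significant, pseudo_qtn, degenerate, pve, model, trait).
#' @export
single_marker_scan <- function(geno, blups, covariates = NULL,
                               trait = "trait", alpha = 0.05) {
  if (!inherits(geno, "geno_matrix")) .fail("`geno` must be a geno_matrix")
  if (anyNA(geno$dosage)) .fail("genotype matrix has missing calls; impute first")
  y <- .align_blups(geno, blups)
  C <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  sc <- .ols_scan(y, geno$dosage, C)
  .assoc_result(geno, sc$effect, sc$p, sc$degenerate,
                pseudo = rep(FALSE, ncol(geno$dosage)),
                model = "single_marker", trait = trait, alpha = alpha)
}

# joint model y ~ C + markers[S]; returns per-S-marker p-values, effects, BIC
.joint_fit <- function(y, C, Gs) {
  X <- cbind(C, Gs)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  k <- fit$rank
  bic <- n * log(rss / n) + k * log(n)
  dfres <- n - k
  dg <- rep(NA_real_, ncol(X))
  R <- fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE]
  Ri <- backsolve(R, diag(k))
  dg[fit$qr$pivot[seq_len(k)]] <- rowSums(Ri^2)
  se <- sqrt(rss / dfres * dg)
  tt <- fit$coefficients / se
  p <- 2 * pt(-abs(tt), df = dfres)
  idx <- ncol(C) + seq_len(ncol(Gs))
  list(p = p[idx], effect = fit$coefficients[idx], bic = bic, rss = rss)
}

# extended BIC (EBIC): BIC + 2 gamma log(m) per selected marker, the
# standard correction for model selection among m >> n candidate markers
.bic_of <- function(y, C, Gs, m, gamma) {
  X <- cbind(C, Gs)
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  k_mark <- if (is.null(Gs)) 0L else ncol(Gs)
  n * log(sum(fit$residuals^2) / n) + fit$rank * log(n) +
    2 * gamma * k_mark * log(m)
}

# shared iteration skeleton of the two multi-locus scans
.multilocus_scan <- function(geno, blups, config, covariates, trait,
                             select_fun) {
  if (!inherits(geno, "geno_matrix")) .fail("`geno` must be a geno_matrix")
  if (anyNA(geno$dosage)) .fail("genotype matrix has missing calls; impute first")
  y <- .align_blups(geno, blups)
  G <- geno$dosage
  m <- ncol(G)
  C0 <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  thr_sig <- config$alpha / m
  thr_cand <- min(thr_sig * config$relax_factor, 0.01)

  S <- integer(0)
  converged <- FALSE
  history <- list()
  for (it in seq_len(config$max_iterations)) {
    C <- if (length(S)) cbind(C0, G[, S, drop = FALSE]) else C0
    sc <- .ols_scan(y, G, C)
    # pseudo-QTNs are collinear with the conditioning set; score them by
    # their unconditioned-on-self scan for candidate ranking
    p_rank <- sc$p
    if (length(S)) {
      scS <- .ols_scan(y, G[, S, drop = FALSE], C0)
      p_rank[S] <- scS$p
    }
    cand <- select_fun(p_rank, thr_cand, G, geno$map, config)
    S_new <- .bic_select(y, C0, G, cand, config)
    # stabilized, or entered a cycle of previously visited sets
    seen <- any(vapply(history, function(s)
      length(s) == length(S_new) && setequal(s, S_new), logical(1)))
    if ((length(S_new) == length(S) && setequal(S_new, S)) || seen) {
      converged <- TRUE
      S <- S_new
      break
    }
    history[[length(history) + 1L]] <- S
    S <- S_new
  }
  C <- if (length(S)) cbind(C0, G[, S, drop = FALSE]) else C0
  sc <- .ols_scan(y, G, C)
  p <- sc$p; eff <- sc$effect; degen <- sc$degenerate
  pseudo <- rep(FALSE, m)
  if (length(S)) {
    jf <- .joint_fit(y, C0, G[, S, drop = FALSE])
    jf$p[is.na(jf$p)] <- 1
    p[S] <- pmin(pmax(jf$p, .Machine$double.xmin), 1)
    eff[S] <- jf$effect
    degen[S] <- FALSE
    pseudo[S] <- TRUE
  }
  .assoc_result(geno, eff, p, degen, pseudo, config$model, trait,
                config$alpha, converged = converged)
}

# greedy forward BIC selection over p-ordered candidates
.bic_select <- function(y, C0, G, cand, config) {
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(cand$p), , drop = FALSE]
  idx <- cand$idx[seq_len(min(nrow(cand), 3 * config$max_pseudo_qtns))]
  m <- ncol(G)
  gam <- config$ebic_gamma
  if (config$model == "blink_like") {
    # EBIC-minimizing prefix of the pruned, p-ordered list
    best <- integer(0)
    best_bic <- .bic_of(y, C0, NULL, m, gam)
    for (k in seq_len(min(length(idx), config$max_pseudo_qtns))) {
      b <- .bic_of(y, C0, G[, idx[seq_len(k)], drop = FALSE], m, gam)
      if (b < best_bic) {
        best_bic <- b
        best <- idx[seq_len(k)]
      }
    }
    sort(best)
  } else {
    sel <- integer(0)
    bic <- .bic_of(y, C0, NULL, m, gam)
    for (i in idx) {
      if (length(sel) >= config$max_pseudo_qtns) break
      b <- .bic_of(y, C0, G[, c(sel, i), drop = FALSE], m, gam)
      if (b < bic) {
        bic <- b
        sel <- c(sel, i)
      }
    }
    sort(sel)
  }
}

# candidate steps ------------------------------------------------------

# best marker per genomic bin among those passing the relaxed screen
.candidates_bin <- function(p, thr, G, map, config) {
  pass <- which(p < thr)
  if (!length(pass)) return(data.frame(idx = integer(0), p = numeric(0)))
  bin <- paste0(map$chrom[pass], ".", map$pos[pass] %/% config$bin_size)
  keep <- tapply(seq_along(pass), bin, function(ii) pass[ii][which.min(p[pass[ii]])])
  data.frame(idx = as.integer(keep), p = p[as.integer(keep)])
}

# p-ordered screen survivors, pruned by pairwise allelic r^2
.candidates_ld <- function(p, thr, G, map, config) {
  pass <- which(p < thr)
  if (!length(pass)) return(data.frame(idx = integer(0), p = numeric(0)))
  pass <- pass[order(p[pass])]
  pass <- pass[seq_len(min(length(pass), 200L))]   # screen cap for tractability
  kept <- integer(0)
  for (i in pass) {
    if (length(kept)) {
      r2 <- suppressWarnings(cor(G[, i], G[, kept, drop = FALSE]))^2
      r2[is.na(r2)] <- 1
      if (any(r2 > config$ld_r2_max)) next
    }
    kept <- c(kept, i)
  }
  data.frame(idx = kept, p = p[kept])
}

#' Multi-locus scan with bin-based pseudo-QTN conditioning
#'
#' Iterative fixed-effect conditioning: scan all markers with the current
#' pseudo-QTN set as covariates, keep the most significant marker per
#' genomic bin among markers passing a relaxed screen, re-select the
#' pseudo-QTN set by greedy forward BIC, and repeat until the set
#' stabilizes. Deterministic given the data and configuration.
#'
#' @inheritParams single_marker_scan
#' @param config a [gwas_config] (model is forced to "farmcpu_like").
#' @return An `assoc_result`; pseudo-QTNs are flagged and carry their
#'   p-values from the final joint model.
#' @export
farmcpu_like_scan <- function(geno, blups, config = gwas_config("farmcpu_like"),
                              covariates = NULL, trait = "trait") {
  config$model <- "farmcpu_like"
  .multilocus_scan(geno, blups, config, covariates, trait, .candidates_bin)
}

#' Multi-locus scan with LD-pruned pseudo-QTN conditioning
#'
#' Same conditioning skeleton as [farmcpu_like_scan] but candidates are
#' pruned by linkage disequilibrium instead of positional bins: screen
#' survivors are taken in p-value order, any candidate with squared
#' allelic correlation above `ld_r2_max` with an already-kept candidate
#' is discarded, and the pseudo-QTN set is the BIC-minimizing prefix of
#' the pruned list.
#'
#' @inheritParams farmcpu_like_scan
#' @export
blink_like_scan <- function(geno, blups, config = gwas_config("blink_like"),
                            covariates = NULL, trait = "trait") {
  config$model <- "blink_like"
  .multilocus_scan(geno, blups, config, covariates, trait, .candidates_ld)
}

#' Per-SNP phenotypic variance explained
#'
#' Fills the `pve` column of an association result. The default is the
#' squared partial correlation: for marker j, 1 - RSS_full / RSS_drop_j,
#' where the full model contains the PCs and all markers in the
#' conditioning set and the reduced model drops marker j. `marginal`
#' instead uses the marginal R^2 of BLUP ~ PCs + marker j alone.
#'
#' @inheritParams single_marker_scan
#' @param result an `assoc_result`.
#' @param markers marker names to fill; default the significant ones.
#' @param type "partial" or "marginal".
#' @return The `assoc_result` with `pve` filled for the chosen markers.
#' @export
snp_pve <- function(geno, blups, result, covariates = NULL,
                    markers = NULL, type = c("partial", "marginal")) {
  type <- match.arg(type)
  y <- .align_blups(geno, blups)
  if (is.null(markers)) markers <- result$marker[result$significant]
  if (!length(markers)) return(result)
  idx <- match(markers, geno$map$marker)
  if (anyNA(idx)) .fail("markers not found in genotype matrix")
  C0 <- cbind(rep(1, length(y)), covariates)
  Gm <- geno$dosage[, idx, drop = FALSE]
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  pve <- numeric(length(idx))
  if (type == "partial") {
    rss_full <- rss(cbind(C0, Gm))
    for (j in seq_along(idx)) {
      rss_red <- rss(cbind(C0, Gm[, -j, drop = FALSE]))
      pve[j] <- if (rss_red > 0) max(0, 1 - rss_full / rss_red) else 0
    }
  } else {
    rss0 <- rss(C0)
    for (j in seq_along(idx))
      pve[j] <- if (rss0 > 0) max(0, 1 - rss(cbind(C0, Gm[, j])) / rss0) else 0
  }
  result$pve[match(markers, result$marker)] <- pmin(pve, 1)
  result
}

#' Cross-model and cross-trait overlap of significant SNPs
#'
#' Summarises a list of association results (or equivalent data.frames
#' with columns model, trait, chrom, pos, pve, significant): per-model
#' unique SNP counts, per model-by-trait SNP counts and total PVE,
#' SNPs detected for more than one trait (pleiotropic), and Venn counts
#' over models. SNP identity is (chromosome, position).
#'
#' @param results list of `assoc_result` objects or compatible
#'   data.frames.
#' @return Object of class `gwas_overlap`: list with `per_model`,
#'   `per_model_trait`, `pleiotropic`, `venn`.
#' @export
overlap_summary <- function(results) {
  if (inherits(results, "data.frame")) results <- list(results)
  if (!length(results)) .fail("need at least one result set")
  sig <- do.call(rbind, lapply(results, function(r) {
    r <- as.data.frame(r)[, c("model", "trait", "chrom", "pos", "pve",
                              "significant")]
    r[r$significant, , drop = FALSE]
  }))
  empty <- data.frame(model = character(0), n_unique_snps = integer(0))
  if (is.null(sig) || nrow(sig) == 0)
    return(structure(list(per_model = empty,
                          per_model_trait = data.frame(),
                          pleiotropic = data.frame(), venn = table(character(0))),
                     class = "gwas_overlap"))
  sig$snp <- paste0(sig$chrom, "_", sig$pos)
  per_model <- aggregate(snp ~ model, sig, function(s) length(unique(s)))
  names(per_model)[2] <- "n_unique_snps"
  pmt <- aggregate(cbind(n_snps = pve) ~ model + trait, sig, length)
  pmt$total_pve <- aggregate(pve ~ model + trait, sig, sum)$pve
  by_snp <- split(sig, sig$snp)
  pleio <- do.call(rbind, lapply(by_snp, function(d) {
    data.frame(snp = d$snp[1],
               traits = paste(sort(unique(d$trait)), collapse = ","),
               models = paste(sort(unique(d$model)), collapse = ","),
               n_traits = length(unique(d$trait)),
               stringsAsFactors = FALSE)
  }))
  pleio <- pleio[pleio$n_traits > 1, , drop = FALSE]
  venn <- table(vapply(by_snp, function(d)
    paste(sort(unique(d$model)), collapse = "&"), ""))
  structure(list(per_model = per_model, per_model_trait = pmt,
                 pleiotropic = pleio, venn = venn),
            class = "gwas_overlap")
}

#' @export
print.gwas_overlap <- function(x, ...) {
  cat("Unique significant SNPs per model:\n")
  print(x$per_model, row.names = FALSE)
  cat("\nPer model x trait (total PVE as fraction):\n")
  print(x$per_model_trait, row.names = FALSE)
  if (nrow(x$pleiotropic)) {
    cat("\nPleiotropic SNPs (detected for >1 trait):\n")
    print(x$pleiotropic[, c("snp", "traits", "models")], row.names = FALSE)
  }
  invisible(x)
}

#' Manhattan- and QQ-plot ready tables
#'
#' @param result an `assoc_result`.
#' @return List with `manhattan` (marker, chrom, pos, neg_log10_p) and
#'   `qq` (expected vs observed -log10 p, uniform quantiles).
#' @export
gwas_tables <- function(result) {
  man <- data.frame(marker = result$marker, chrom = result$chrom,
                    pos = result$pos, neg_log10_p = -log10(result$p_value))
  po <- sort(result$p_value)
  qq <- data.frame(expected = -log10(stats::ppoints(length(po))),
                   observed = -log10(po))
  list(manhattan = man, qq = qq)
}
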