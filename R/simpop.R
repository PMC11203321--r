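# Multi-parent DH population simulator.
#
# The generator emulates the structure of a maize association panel built
# by doubling gametes of F1 hybrids: founder inbreds carry binary
# haplotypes, each cross recombines two founder haplotypes (Haldane
# no-interference model: crossover count per chromosome is Poisson with
# mean equal to the map length in Morgans, crossover positions uniform on
# the genetic map), and the recombinant gamete is doubled so every line is
# fully homozygous.

#' Simulate founder haplotypes
#'
#' Draws one binary haplotype per founder inbred. Per-marker allele
#' frequencies across founders are Uniform(0.1, 0.9) so the panel
#' segregates at essentially every marker; map positions are evenly spaced
#' along each chromosome, with physical positions laid out at roughly
#' 1 Mb per cM.
#'
#' @param n_founders number of founder inbreds (>= 2).
#' @param n_markers total marker count across the genome.
#' @param n_chromosomes number of chromosomes (default 10, as in maize).
#' @param chrom_length_cM genetic length of each chromosome in centimorgans.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `founder_set`: list with `haplotypes`
#'   (founders x markers 0/1 matrix), `map` (marker, chrom, pos, pos_cm)
#'   and `chrom_length_cM`.
#' @examples
#' f <- simulate_founders(4, 100, n_chromosomes = 2, seed = 1)
#' dim(f$haplotypes)
#' @export
simulate_founders <- function(n_founders, n_markers, n_chromosomes = 10,
                              chrom_length_cM = 150, seed = NULL) {
  n_founders <- .check_count(n_founders, "n_founders", min = 2L)
  n_markers <- .check_count(n_markers, "n_markers", min = 1L)
  n_chromosomes <- .check_count(n_chromosomes, "n_chromosomes", min = 1L)
  if (n_markers < n_chromosomes)
    .fail("need at least one marker per chromosome")
  if (!is.finite(chrom_length_cM) || chrom_length_cM <= 0)
    .fail("`chrom_length_cM` must be positive")
  .set_seed(seed)

  per_chrom <- diff(floor(seq(0, n_markers, length.out = n_chromosomes + 1)))
  map <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch) {
    m <- per_chrom[ch]
    pos_cm <- seq(0, chrom_length_cM, length.out = max(m, 2))[seq_len(m)]
    pos_bp <- round(1e4 + pos_cm * 1e6)      # ~1 Mb per cM
    pos_bp <- pos_bp + seq_len(m)            # guarantee strict increase
    data.frame(marker = paste0(ch, "_", pos_bp), chrom = ch,
               pos = pos_bp, pos_cm = pos_cm, stringsAsFactors = FALSE)
  }))
  freq <- runif(n_markers, 0.1, 0.9)
  hap <- matrix(rbinom(n_founders * n_markers, 1L, rep(freq, each = n_founders)),
                nrow = n_founders, ncol = n_markers,
                dimnames = list(sprintf("F%02d", seq_len(n_founders)), map$marker))
  structure(list(haplotypes = hap, map = map,
                 chrom_length_cM = chrom_length_cM),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("founder_set: %d founders, %d markers on %d chromosome(s) (%g cM each)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$map$chrom)), x$chrom_length_cM))
  invisible(x)
}

# one recombinant gamete from two parental haplotypes (vectors over the
# whole genome), under Haldane's no-interference model
.recombine_gamete <- function(hapA, hapB, map, chrom_length_cM) {
  out <- hapA
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    L <- chrom_length_cM
    k <- rpois(1L, L / 100)
    cuts <- if (k > 0) sort(runif(k, 0, L)) else numeric(0)
    phase <- (findInterval(map$pos_cm[idx], cuts) + rbinom(1L, 1L, 0.5)) %% 2L
    out[idx] <- ifelse(phase == 0L, hapA[idx], hapB[idx])
  }
  out
}

#' Simulate a multi-parent DH population
#'
#' Each cross pairs two founders; every line of a cross is an independent
#' doubled gamete of that cross's F1, so all genotype calls are homozygous
#' (dosage 0 or 2) and each line's haplotype is a mosaic of exactly its
#' two parental founder haplotypes.
#'
#' @param founders a [founder_set].
#' @param n_crosses number of crosses (ignored when `crosses` is given).
#' @param lines_per_cross scalar or vector (length `n_crosses`) of DH
#'   lines per cross.
#' @param crosses optional integer matrix (n_crosses x 2) of founder
#'   indices; defaults to random distinct pairs.
#' @param seed optional integer seed.
#' @return An object of class `dh_population`: list with `geno` (a
#'   [geno_matrix] with dosages in \{0, 2\}) and `pedigree` (line, cross,
#'   parent1, parent2).
#' @examples
#' f <- simulate_founders(4, 50, n_chromosomes = 1, seed = 1)
#' pop <- simulate_dh_population(f, n_crosses = 2, lines_per_cross = 5, seed = 2)
#' table(pop$geno$dosage)
#' @export
simulate_dh_population <- function(founders, n_crosses, lines_per_cross,
                                   crosses = NULL, seed = NULL) {
  if (!inherits(founders, "founder_set")) .fail("`founders` must be a founder_set")
  nf <- nrow(founders$haplotypes)
  .set_seed(seed)
  if (is.null(crosses)) {
    n_crosses <- .check_count(n_crosses, "n_crosses")
    crosses <- t(replicate(n_crosses, sample.int(nf, 2L)))
  } else {
    crosses <- as.matrix(crosses)
    n_crosses <- nrow(crosses)
  }
  if (any(crosses < 1 | crosses > nf) || any(crosses != round(crosses)))
    .fail(sprintf("cross references founder outside 1..%d", nf))
  if (length(lines_per_cross) == 1L)
    lines_per_cross <- rep(.check_count(lines_per_cross, "lines_per_cross"), n_crosses)
  if (length(lines_per_cross) != n_crosses)
    .fail("`lines_per_cross` must be scalar or one value per cross")

  n_lines <- sum(lines_per_cross)
  dosage <- matrix(0, n_lines, ncol(founders$haplotypes))
  ped <- data.frame(line = sprintf("L%04d", seq_len(n_lines)),
                    cross = rep(seq_len(n_crosses), lines_per_cross),
                    parent1 = rep(crosses[, 1], lines_per_cross),
                    parent2 = rep(crosses[, 2], lines_per_cross),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_lines)) {
    hapA <- founders$haplotypes[ped$parent1[i], ]
    hapB <- founders$haplotypes[ped$parent2[i], ]
    dosage[i, ] <- 2 * .recombine_gamete(hapA, hapB, founders$map,
                                         founders$chrom_length_cM)
  }
  rownames(dosage) <- ped$line
  structure(list(geno = geno_matrix(dosage, founders$map), pedigree = ped),
            class = "dh_population")
}

#' @export
print.dh_population <- function(x, ...) {
  cat(sprintf("dh_population: %d DH lines from %d cross(es)\n",
              nrow(x$geno$dosage), length(unique(x$pedigree$cross))))
  print(x$geno)
  invisible(x)
}

#' Define a trait architecture for phenotype simulation
#'
#' Builds an additive architecture of one major QTL plus geometrically
#' decaying minor QTLs shared across traits (pleiotropy), with minor-QTL
#' effect vectors correlated across traits. The major QTL's share of
#' genetic variance is chosen so that its phenotypic variance explained
#' (PVE) is approximately `major_pve` at the implied entry-mean
#' heritability.
#'
#' @param pop a [dh_population] (used to pick segregating QTLs and
#'   calibrate the major-QTL effect against realized dosage variances).
#' @param traits character vector of trait names.
#' @param n_qtl number of QTLs (including the major one).
#' @param major_pve target phenotypic variance explained by the major QTL.
#' @param components numeric matrix (traits x 3) of target variance
#'   components (columns sigma2_g, sigma2_ge, sigma2_e), in days^2.
#'   Defaults emulate a high-heritability flowering-time panel.
#' @param effect_cor correlation matrix (traits x traits) for minor-QTL
#'   effect vectors, or a single scalar used for every pair.
#' @param mu trait means in days.
#' @param E,R environment and replicate counts.
#' @param env_sd standard deviation (days) of the fixed environment offsets.
#' @param decay geometric decay rate of minor-QTL effect magnitudes
#'   (near 1 = an evenly polygenic background; lower values concentrate
#'   the signal in a handful of loci).
#' @param seed optional integer seed.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(pop, traits = c("DTT", "DTP", "DTS"),
                               n_qtl = 300, major_pve = 0.15,
                               components = NULL, effect_cor = NULL,
                               mu = NULL, E = 4, R = 2, env_sd = 6,
                               decay = 0.995, seed = NULL) {
  if (!inherits(pop, "dh_population")) .fail("`pop` must be a dh_population")
  n_qtl <- .check_count(n_qtl, "n_qtl")
  E <- .check_count(E, "E"); R <- .check_count(R, "R")
  nt <- length(traits)
  if (is.null(components))
    components <- matrix(c(13.61, 9.22, 4.26,
                           19.84, 10.68, 4.29,
                           23.98, 14.12, 4.92)[seq_len(3 * nt)],
                         nrow = nt, byrow = TRUE)
  components <- matrix(as.numeric(components), nrow = nt,
                       dimnames = list(traits, c("sigma2_g", "sigma2_ge", "sigma2_e")))
  if (any(components < 0)) .fail("target variances must be non-negative")
  if (is.null(mu)) mu <- c(60.55, 65.00, 66.30)[seq_len(nt)]
  if (is.null(effect_cor)) {
    effect_cor <- matrix(0.90, nt, nt)
    if (nt == 3) effect_cor[2, 3] <- effect_cor[3, 2] <- 0.95
    if (nt == 3) effect_cor[1, 3] <- effect_cor[3, 1] <- 0.88
    diag(effect_cor) <- 1
  } else if (length(effect_cor) == 1L) {
    rho <- effect_cor
    effect_cor <- matrix(rho, nt, nt); diag(effect_cor) <- 1
  }
  .set_seed(seed)

  X <- pop$geno$dosage
  v <- apply(X, 2, var)
  seg <- which(v > 0)
  if (length(seg) < n_qtl) .fail("not enough segregating markers for n_qtl")
  qtl <- sort(sample(seg, n_qtl))
  major <- qtl[which.max(v[qtl])]

  # correlated minor effects: traits x (n_qtl - 1), geometric magnitude decay
  minors <- setdiff(qtl, major)
  Z <- matrix(rnorm(nt * length(minors)), nt)
  Lc <- t(chol(effect_cor))
  eff_minor <- (Lc %*% Z) * rep(decay^seq_along(minors), each = nt)

  effects <- matrix(0, nt, n_qtl, dimnames = list(traits, colnames(X)[qtl]))
  effects[, match(minors, qtl)] <- eff_minor
  # calibrate major effect so var share of g is ~ major_pve / H2 per trait
  for (t in seq_len(nt)) {
    H2 <- heritability_entry_mean(components[t, 1], components[t, 2],
                                  components[t, 3], E = E, R = R)
    f <- min(major_pve / max(H2, 1e-8), 0.95)     # share of genetic variance
    g_minor <- X[, minors, drop = FALSE] %*% eff_minor[t, ]
    vm <- var(as.vector(g_minor))
    effects[t, match(major, qtl)] <- sqrt(f / (1 - f) * vm / v[major])
  }
  structure(list(traits = traits, qtl_indices = qtl, major_qtl = major,
                 effects = effects, components = components, mu = mu,
                 E = E, R = R, env_sd = env_sd, effect_cor = effect_cor),
            class = "trait_architecture")
}

#' Simulate multi-environment phenotypes
#'
#' Phenotypes follow the two-way model y_ijk = mu + g_i + e_j + (ge)_ij +
#' eps_ijk per trait: the genetic value g_i is the additive QTL score,
#' centered and rescaled so its sample variance equals the target sigma2_g
#' exactly; environment main effects are fixed offsets drawn once per
#' environment; the genotype-by-environment deviations and plot residuals
#' are normals with the target sigma2_ge and sigma2_e. Because the traits
#' of one line are scored on the same plots, the non-genetic deviations
#' are correlated across traits with the architecture's trait correlation
#' matrix (weather and management shift all flowering dates of a plot
#' together).
#'
#' @param pop a [dh_population].
#' @param arch a [trait_architecture].
#' @param seed optional integer seed.
#' @return List of class `sim_phenotypes` with `book` (long data.frame:
#'   line, env, rep, trait, value), `truth` (line, trait, tbv = mu + g),
#'   and `env_effects`.
#' @export
simulate_phenotypes <- function(pop, arch, seed = NULL) {
  if (!inherits(pop, "dh_population")) .fail("`pop` must be a dh_population")
  if (!inherits(arch, "trait_architecture")) .fail("`arch` must be a trait_architecture")
  X <- pop$geno$dosage
  if (max(arch$qtl_indices) > ncol(X)) .fail("architecture QTLs outside marker set")
  .set_seed(seed)
  E <- arch$E; R <- arch$R
  n <- nrow(X)
  lines <- rownames(X)
  envs <- sprintf("E%d", seq_len(E))
  env_off <- rnorm(E, 0, arch$env_sd)
  names(env_off) <- envs

  nt <- length(arch$traits)
  Lc <- t(chol(arch$effect_cor))
  # standard-normal deviations shared across traits at the plot level
  ge_z <- Lc %*% matrix(rnorm(nt * n * E), nt)
  eps_z <- Lc %*% matrix(rnorm(nt * n * E * R), nt)
  rec <- expand.grid(line = seq_len(n), env = seq_len(E), rep = seq_len(R),
                     KEEP.OUT.ATTRS = FALSE)

  books <- vector("list", nt)
  truth <- vector("list", nt)
  for (t in seq_along(arch$traits)) {
    tr <- arch$traits[t]
    s2g <- arch$components[t, 1]; s2ge <- arch$components[t, 2]
    s2e <- arch$components[t, 3]
    g_raw <- as.vector(X[, arch$qtl_indices, drop = FALSE] %*% arch$effects[t, ])
    vr <- var(g_raw)
    if (vr <= 0 && s2g > 0)
      .fail("zero genetic variance with nonzero requested heritability")
    g <- if (s2g > 0) (g_raw - mean(g_raw)) * sqrt(s2g / vr) else rep(0, n)
    ge <- matrix(sqrt(s2ge) * ge_z[t, ], n, E)
    val <- arch$mu[t] + g[rec$line] + env_off[rec$env] +
      ge[cbind(rec$line, rec$env)] +
      sqrt(s2e) * eps_z[t, seq_len(nrow(rec))]
    books[[t]] <- data.frame(line = lines[rec$line], env = envs[rec$env],
                             rep = rec$rep, trait = tr, value = val,
                             stringsAsFactors = FALSE)
    truth[[t]] <- data.frame(line = lines, trait = tr, tbv = arch$mu[t] + g,
                             stringsAsFactors = FALSE)
  }
  structure(list(book = do.call(rbind, books), truth = do.call(rbind, truth),
                 env_effects = env_off, arch = arch),
            class = "sim_phenotypes")
}

#' Inject missing genotype calls
#'
#' Masks each call independently with probability `rate` (sets it to
#' `NA`); used to exercise the missing-rate filter and imputation.
#'
#' @param geno a [geno_matrix].
#' @param rate per-call missing probability in [0, 1).
#' @param seed optional integer seed.
#' @return A [geno_matrix] with calls masked.
#' @export
inject_missingness <- function(geno, rate, seed = NULL) {
  if (!inherits(geno, "geno_matrix")) .fail("`geno` must be a geno_matrix")
  rate <- .check_fraction(rate, "rate", 0, 1, open_hi = TRUE)
  if (rate == 0) return(geno)
  .set_seed(seed)
  d <- geno$dosage
  d[runif(length(d)) < rate] <- NA_real_
  geno_matrix(d, geno$map)
}
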