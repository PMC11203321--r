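# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 200-line, 800-marker panel with the default (polygenic) architecture
small_panel <- function() {
  cached("small_panel", function() {
    f <- simulate_founders(8, 800, n_chromosomes = 4, seed = 11)
    pop <- simulate_dh_population(f, 10, 20, seed = 12)
    arch <- trait_architecture(pop, n_qtl = 150, decay = 0.99, seed = 13)
    sim <- simulate_phenotypes(pop, arch, seed = 14)
    list(founders = f, pop = pop, arch = arch, sim = sim)
  })
}

small_blups <- function() {
  cached("small_blups", function() blup_table(small_panel()$sim$book))
}

# tiny deterministic genotype matrix for hand-checkable oracles
toy_geno <- function(n = 20, m = 5, seed = 7) {
  set.seed(seed)
  d <- matrix(2 * rbinom(n * m, 1, 0.5), n, m)
  geno_matrix(d, data.frame(marker = paste0("1_", 100 * seq_len(m)),
                            chrom = 1, pos = 100 * seq_len(m)))
}

# balanced phenotype book with known generating values
balanced_book <- function(n_lines, E, R, s2g, s2ge, s2e, mu = 60, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_lines, 0, sqrt(s2g))
  env_off <- rnorm(E, 0, 3)
  ge <- matrix(rnorm(n_lines * E, 0, sqrt(s2ge)), n_lines, E)
  rec <- expand.grid(line = seq_len(n_lines), env = seq_len(E),
                     rep = seq_len(R))
  data.frame(line = sprintf("L%03d", rec$line),
             env = sprintf("E%d", rec$env), rep = rec$rep, trait = "T1",
             value = mu + g[rec$line] + env_off[rec$env] +
               ge[cbind(rec$line, rec$env)] + rnorm(nrow(rec), 0, sqrt(s2e)))
}
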