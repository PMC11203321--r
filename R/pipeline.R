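# End-to-end orchestration: fixture generation and the staged pipeline
# simulate/ingest -> phenostats -> genoqc -> gwas -> genes -> gs, with all
# stage outputs written as TSV and a manifest of checksums.

#' Read a long-format phenotype table
#'
#' Tab-separated with header `line, env, rep, trait, value`.
#'
#' @param path TSV path.
#' @return data.frame phenotype book.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .fail(sprintf("file not found: %s", path))
  b <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .check_book(b)
}

#' Write a long-format phenotype table
#'
#' Values are rounded to 0.1 day on export only (field phenologists score
#' flowering to the day or half-day; internal computations keep full
#' precision).
#'
#' @param book phenotype data.frame.
#' @param path output TSV path.
#' @param round_digits decimals to keep on export (default 1).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(book, path, round_digits = 1) {
  b <- .check_book(book)
  b$value <- round(b$value, round_digits)
  write.table(b, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a self-contained analysis fixture
#'
#' Simulates a multi-parent DH panel with three correlated flowering
#' traits in a multi-environment trial, and writes every input the
#' pipeline consumes: genotypes (VCF), phenotypes (long TSV), a synthetic
#' gene annotation (GFF3, genes placed near a subset of markers), and
#' truth tables (QTL positions/effects and true breeding values) for
#' recovery tests.
#'
#' `scale = "small"` is a 200-line, 1,000-marker panel that builds in
#' seconds; `scale = "paper_like"` emulates the full study design: 379 DH
#' lines from 21 crosses, 4 environments, 2 replicates, 3 traits (marker
#' count reduced to 5,000 for desk-scale work).
#'
#' @param dir output directory (created if needed).
#' @param scale "small" or "paper_like".
#' @param seed integer seed.
#' @return Named list of file paths, invisibly; also returns the
#'   simulated objects in `$objects`.
#' @export
make_fixture <- function(dir, scale = c("small", "paper_like"), seed = 1) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (scale == "small") {
    n_founders <- 8; n_markers <- 1000; n_chrom <- 5
    crosses <- 10; lpc <- rep(20, 10)            # 200 lines
    n_qtl <- 20
  } else {
    n_founders <- 42; n_markers <- 5000; n_chrom <- 10
    crosses <- 21; lpc <- c(rep(18, 20), 19)     # 379 lines
    n_qtl <- 300
  }
  founders <- simulate_founders(n_founders, n_markers, n_chrom,
                                seed = .child_seed(seed, 1))
  pop <- simulate_dh_population(founders, crosses, lpc,
                                seed = .child_seed(seed, 2))
  arch <- trait_architecture(pop, n_qtl = n_qtl, seed = .child_seed(seed, 3))
  sim <- simulate_phenotypes(pop, arch, seed = .child_seed(seed, 4))

  paths <- list(genotype = file.path(dir, "genotypes.vcf"),
                phenotype = file.path(dir, "phenotypes.tsv"),
                gff = file.path(dir, "genes.gff3"),
                truth_qtl = file.path(dir, "truth_qtl.tsv"),
                truth_tbv = file.path(dir, "truth_tbv.tsv"))
  write_genotypes(pop$geno, paths$genotype, "vcf")
  write_phenotypes(sim$book, paths$phenotype, round_digits = 6)

  # synthetic annotation: one gene framing every 10th marker
  map <- pop$geno$map
  pick <- map[seq(1, nrow(map), by = 10), ]
  genes <- data.frame(gene_id = sprintf("SYNGENE%04d", seq_len(nrow(pick))),
                      chrom = pick$chrom,
                      start = pmax(1, pick$pos - 2000),
                      end = pick$pos + 2000, strand = "+",
                      description = "synthetic gene model",
                      stringsAsFactors = FALSE)
  write_gff3(genes, paths$gff)

  qtl_truth <- data.frame(marker = colnames(pop$geno$dosage)[arch$qtl_indices],
                          chrom = map$chrom[arch$qtl_indices],
                          pos = map$pos[arch$qtl_indices],
                          major = arch$qtl_indices == arch$major_qtl,
                          t(arch$effects))
  write.table(qtl_truth, paths$truth_qtl, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, paths$truth_tbv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- paths
  out$objects <- list(founders = founders, pop = pop, arch = arch, sim = sim)
  invisible(out)
}

#' Assemble and validate a pipeline configuration
#'
#' @param genotype,phenotype,gff input file paths.
#' @param out_dir output directory.
#' @param maf_min,missing_max marker QC thresholds.
#' @param n_pcs PC covariates for the scans.
#' @param models GWAS models to run.
#' @param alpha Bonferroni level.
#' @param window_bp candidate-gene half-window.
#' @param gs_k,gs_reps genomic-selection CV design.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype, phenotype, gff, out_dir,
                            maf_min = 0.05, missing_max = 0.20, n_pcs = 3,
                            models = c("farmcpu_like", "blink_like"),
                            alpha = 0.05, window_bp = 10000,
                            gs_k = 5, gs_reps = 10, seed = 1) {
  cfg <- structure(list(genotype = genotype, phenotype = phenotype, gff = gff,
                        out_dir = out_dir, maf_min = maf_min,
                        missing_max = missing_max, n_pcs = n_pcs,
                        models = models, alpha = alpha, window_bp = window_bp,
                        gs_k = gs_k, gs_reps = gs_reps, seed = seed),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_config <- function(config) {
  for (p in c("genotype", "phenotype", "gff")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      .fail(sprintf("config error: %s path missing or does not exist (%s)",
                    p, config[[p]]), class = "config_error")
  }
  invisible(config)
}

.stage_write <- function(obj, file) {
  write.table(obj, file, sep = "\t", quote = FALSE, row.names = FALSE)
  file
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> phenotype statistics -> genotype QC -> GWAS ->
#' candidate genes -> genomic selection, each stage consuming the
#' previous stage's in-memory objects and writing its TSV outputs under
#' `config$out_dir`. Rerunning with the same config and seed reproduces
#' all data outputs bit-identically (timings aside).
#'
#' @param config a validated [pipeline_config].
#' @return Manifest data.frame (stage, file, md5, seconds), invisibly;
#'   attribute `results` holds the in-memory stage objects.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, files, secs) {
    if (!length(files)) files <- NA_character_
    md5 <- rep(NA_character_, length(files))
    ok <- !is.na(files)
    if (any(ok)) md5[ok] <- unname(tools::md5sum(files[ok]))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = unname(files), md5 = md5, seconds = secs,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[3]
    out <- tryCatch(fun(), error = function(e)
      .fail(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "stage_error"))
    note(stage, out$files, round(proc.time()[3] - t0, 3))
    out$value
  }
  od <- function(f) file.path(config$out_dir, f)

  ingest <- run_stage("ingest", function() {
    geno <- read_genotypes(config$genotype)
    book <- read_phenotypes(config$phenotype)
    list(value = list(geno = geno, book = book), files = character(0))
  })
  ph <- run_stage("phenostats", function() {
    ds <- descriptive_stats(ingest$book)
    blups <- blup_table(ingest$book)
    vcs <- attr(blups, "varcomp")
    vtab <- do.call(rbind, lapply(vcs, function(v)
      data.frame(trait = v$trait, sigma2_g = v$sigma2_g,
                 sigma2_ge = v$sigma2_ge, sigma2_e = v$sigma2_e,
                 E = v$E, R = v$R, H2_percent = 100 * v$H2)))
    f <- c(.stage_write(ds, od("descriptive_stats.tsv")),
           .stage_write(vtab, od("variance_components.tsv")),
           .stage_write(blups, od("blups.tsv")))
    list(value = list(blups = blups, varcomp = vcs, desc = ds), files = f)
  })
  qc <- run_stage("genoqc", function() {
    fl <- filter_markers(ingest$geno, config$maf_min, config$missing_max)
    imp <- impute_mean(fl$geno)
    pcs <- pca_covariates(imp, config$n_pcs)
    rep_df <- data.frame(markers_in = fl$report$markers_in,
                         markers_out = fl$report$markers_out,
                         removed_by_missing = fl$report$removed_by_missing,
                         removed_by_maf = fl$report$removed_by_maf)
    f <- c(.stage_write(rep_df, od("qc_report.tsv")),
           .stage_write(data.frame(line = rownames(pcs), pcs,
                                   row.names = NULL), od("pc_scores.tsv")))
    list(value = list(geno = imp, pcs = pcs, report = fl$report), files = f)
  })
  traits <- setdiff(names(ph$blups), "line")
  gwas <- run_stage("mlgwas", function() {
    res <- list(); files <- character(0)
    for (model in config$models) for (tr in traits) {
      cfgm <- gwas_config(model, alpha = config$alpha, n_pcs = config$n_pcs)
      y <- setNames(ph$blups[[tr]], ph$blups$line)
      r <- switch(model,
                  farmcpu_like = farmcpu_like_scan(qc$geno, y, cfgm, qc$pcs, tr),
                  blink_like = blink_like_scan(qc$geno, y, cfgm, qc$pcs, tr),
                  single_marker = single_marker_scan(qc$geno, y, qc$pcs, tr,
                                                     config$alpha))
      r <- snp_pve(qc$geno, y, r, qc$pcs)
      res[[paste(model, tr, sep = ".")]] <- r
      files <- c(files,
                 .stage_write(as.data.frame(r),
                              od(sprintf("assoc_%s_%s.tsv", model, tr))))
      tabs <- gwas_tables(r)
      files <- c(files,
                 .stage_write(tabs$manhattan,
                              od(sprintf("manhattan_%s_%s.tsv", model, tr))),
                 .stage_write(tabs$qq, od(sprintf("qq_%s_%s.tsv", model, tr))))
    }
    ov <- overlap_summary(res)
    files <- c(files, .stage_write(ov$per_model, od("overlap_per_model.tsv")))
    list(value = list(results = res, overlap = ov), files = files)
  })
  genes <- run_stage("genewin", function() {
    gset <- load_gff(config$gff)
    sig <- do.call(rbind, lapply(gwas$results, function(r)
      as.data.frame(r)[r$significant,
                       c("marker", "chrom", "pos", "trait"), drop = FALSE]))
    hits <- if (!is.null(sig) && nrow(sig)) {
      names(sig)[1] <- "snp"
      query_window(unique(sig), gset, config$window_bp)
    } else query_window(data.frame(snp = character(0), chrom = character(0),
                                   pos = integer(0)), gset, config$window_bp)
    f <- .stage_write(as.data.frame(hits), od("candidate_genes.tsv"))
    list(value = list(genes = gset, hits = hits), files = f)
  })
  gs <- run_stage("gspredict", function() {
    rows <- list()
    for (tr in traits) {
      y <- setNames(ph$blups[[tr]], ph$blups$line)
      rows[[tr]] <- cross_validate(qc$geno, y, k = config$gs_k,
                                   reps = config$gs_reps, trait = tr,
                                   seed = .child_seed(config$seed,
                                                      match(tr, traits)))
    }
    tab <- do.call(rbind, rows)
    f <- .stage_write(as.data.frame(tab), od("gs_accuracy.tsv"))
    list(value = list(accuracy = tab), files = f)
  })

  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  attr(man, "results") <- list(phenostats = ph, qc = qc, gwas = gwas,
                               genes = genes, gs = gs)
  invisible(man)
}
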