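# Genotype I/O, marker QC filters, mean imputation, and PCA covariates.

#' Read genotypes from VCF or HapMap
#'
#' VCF is parsed with the vcfR package; only biallelic SNPs are kept
#' (multi-allelic and non-SNP records are dropped and tallied). Dosage is
#' the alternate-allele count per line (0, 1, 2, or NA); heterozygous
#' calls in a declared-DH dataset are counted and reported via
#' [n_het()]. HapMap-format tables use the standard 11 metadata columns
#' followed by one two-letter genotype per line.
#'
#' @param path file path.
#' @param format "auto" (by extension), "vcf", or "hapmap".
#' @return A [geno_matrix]. Attributes `n_multiallelic_dropped` and
#'   `n_nonsnp_dropped` record filtered records.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (!file.exists(path)) .fail(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "hapmap"
  if (format == "vcf") .read_vcf(path) else .read_hapmap(path)
}

.read_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "##fileformat=VCF"))
    .fail(sprintf("malformed VCF header at line 1 of %s: expected ##fileformat=VCF...",
                  path), class = "format_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    gm <- geno_matrix(matrix(numeric(0), nrow = 0, ncol = 0),
                      data.frame(marker = character(0), chrom = character(0),
                                 pos = integer(0)))
    # no samples x no markers: still return line ids from the header
    samples <- colnames(v@gt)[-1]
    gm$dosage <- matrix(numeric(0), nrow = length(samples), ncol = 0,
                        dimnames = list(samples, NULL))
    return(gm)
  }
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  d1 <- suppressWarnings(as.numeric(allele1))
  d2 <- suppressWarnings(as.numeric(allele2))
  dos <- d1 + d2
  dos[is.na(d1) | is.na(d2)] <- NA_real_
  dosage <- t(matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt)))
  id <- fix$ID
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  map <- data.frame(marker = id, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  gm <- geno_matrix(dosage[, ord, drop = FALSE], map[ord, , drop = FALSE])
  attr(gm, "n_multiallelic_dropped") <- sum(multi)
  attr(gm, "n_nonsnp_dropped") <- sum(!snp & !multi)
  gm
}

.HMP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
               "center", "protLSID", "assayLSID", "panel", "QCcode")

.read_hapmap <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12)
    .fail("HapMap table needs 11 metadata columns plus at least one sample",
          class = "format_error")
  samples <- names(tab)[-(1:11)]
  alleles <- strsplit(tab[[2]], "/", fixed = TRUE)
  ref <- vapply(alleles, `[`, "", 1)
  alt <- vapply(alleles, `[`, "", 2)
  G <- as.matrix(tab[, -(1:11), drop = FALSE])
  dosage <- matrix(NA_real_, nrow = length(samples), ncol = nrow(tab),
                   dimnames = list(samples, tab[[1]]))
  for (j in seq_len(nrow(tab))) {
    g <- G[j, ]
    dosage[, j] <- (substr(g, 1, 1) == alt[j]) + (substr(g, 2, 2) == alt[j])
    dosage[g %in% c("NN", "N", "--", ""), j] <- NA_real_
  }
  map <- data.frame(marker = tab[[1]], chrom = tab[[3]],
                    pos = as.integer(tab[[4]]), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  geno_matrix(dosage[, ord, drop = FALSE], map[ord, , drop = FALSE])
}

#' Write genotypes to VCF v4.2 or HapMap text
#'
#' Dosages must be whole calls (0, 1, 2, or NA); imputed fractional
#' dosages cannot be serialized as genotype calls. REF/ALT default to A/C
#' when the map does not carry allele columns.
#'
#' @param geno a [geno_matrix].
#' @param path output file path.
#' @param format "vcf" or "hapmap".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "hapmap")) {
  format <- match.arg(format)
  d <- geno$dosage
  if (!all(d[!is.na(d)] %in% c(0, 1, 2)))
    .fail("dosages must be 0/1/2/NA to serialize as genotype calls")
  map <- geno$map
  ref <- if ("ref" %in% names(map)) map$ref else rep("A", nrow(map))
  alt <- if ("alt" %in% names(map)) map$alt else rep("C", nrow(map))
  if (format == "vcf") {
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0] <- "0/0"
    gt[!is.na(d) & d == 1] <- "0/1"
    gt[!is.na(d) & d == 2] <- "1/1"
    header <- c("##fileformat=VCFv4.2",
                "##source=flowerGS",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(d)), collapse = "\t"))
    body <- if (ncol(d)) {
      rows <- cbind(map$chrom, map$pos, map$marker, ref, alt, ".", ".", ".",
                    "GT", t(gt))
      apply(rows, 1, paste, collapse = "\t")
    } else character(0)
    writeLines(c(header, body), path)
  } else {
    code <- function(x, rf, al) {
      out <- rep("NN", length(x))
      out[!is.na(x) & x == 0] <- paste0(rf, rf)
      out[!is.na(x) & x == 1] <- paste0(rf, al)
      out[!is.na(x) & x == 2] <- paste0(al, al)
      out
    }
    gt <- vapply(seq_len(ncol(d)), function(j) code(d[, j], ref[j], alt[j]),
                 character(nrow(d)))
    gt <- matrix(gt, nrow = nrow(d))
    tab <- data.frame(map$marker, paste0(ref, "/", alt), map$chrom, map$pos,
                      "+", ".", ".", ".", ".", ".", ".",
                      t(gt), check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- c(.HMP_META, rownames(d))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter markers by missing rate and minor allele frequency
#'
#' Sequential filters: first keep markers with missing rate strictly
#' below `missing_max`, then (on the survivors, with MAF computed on
#' non-missing calls) keep markers with MAF strictly above `maf_min`.
#' Strict inequalities: a marker at exactly the threshold is removed.
#'
#' @param geno a [geno_matrix].
#' @param maf_min minimum minor allele frequency (exclusive), default 0.05.
#' @param missing_max maximum missing rate (exclusive), default 0.20.
#' @return List with `geno` (filtered [geno_matrix]) and `report`
#'   (class `qc_report`: markers_in, markers_out, removed_by_missing,
#'   removed_by_maf, thresholds).
#' @export
filter_markers <- function(geno, maf_min = 0.05, missing_max = 0.20) {
  if (!inherits(geno, "geno_matrix")) .fail("`geno` must be a geno_matrix")
  maf_min <- .check_fraction(maf_min, "maf_min")
  missing_max <- .check_fraction(missing_max, "missing_max")
  m_in <- ncol(geno$dosage)
  mr <- missing_rate(geno)
  keep1 <- mr < missing_max
  g1 <- geno[, which(keep1)]
  f <- maf(g1)
  keep2 <- !is.nan(f) & f > maf_min
  out <- g1[, which(keep2)]
  report <- structure(list(markers_in = m_in, markers_out = ncol(out$dosage),
                           removed_by_missing = sum(!keep1),
                           removed_by_maf = sum(!keep2),
                           thresholds = c(maf_min = maf_min,
                                          missing_max = missing_max)),
                      class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Marker QC: %d in -> %d retained (%d removed: %d by missing rate >= %g, %d by MAF <= %g)\n",
              x$markers_in, x$markers_out,
              x$removed_by_missing + x$removed_by_maf,
              x$removed_by_missing, x$thresholds["missing_max"],
              x$removed_by_maf, x$thresholds["maf_min"]))
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call by the marker's mean dosage over non-missing
#' calls; observed calls are unchanged. Appropriate for DH panels, where
#' homozygosity makes model-based imputation unnecessary; documented as a
#' swap point for more sophisticated schemes.
#'
#' @param geno a [geno_matrix].
#' @return A [geno_matrix] with no missing values (dosages may be
#'   fractional).
#' @export
impute_mean <- function(geno) {
  if (!inherits(geno, "geno_matrix")) .fail("`geno` must be a geno_matrix")
  d <- geno$dosage
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas) == 0) return(geno)
  cm <- colMeans(d, na.rm = TRUE)
  if (any(is.nan(cm[unique(nas[, 2])]))) {
    bad <- colnames(d)[unique(nas[, 2])[is.nan(cm[unique(nas[, 2])])]]
    .fail(sprintf("all calls missing for marker(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  d[nas] <- cm[nas[, 2]]
  geno_matrix(d, geno$map)
}

#' Principal-component covariates for population structure
#'
#' Eigen-decomposition of the column-centered dosage matrix (via
#' [stats::prcomp]); components are ordered by decreasing explained
#' variance and signs are fixed so each component's largest-magnitude
#' loading is positive (making scores invariant, up to numerical noise,
#' to marker order).
#'
#' @param geno a complete (imputed) [geno_matrix].
#' @param n_components number of PCs to return (default 3, the number
#'   typically used to control structure in association scans).
#' @return Numeric matrix (lines x n_components) of PC scores, with
#'   attribute `explained` (fraction of variance per component).
#' @export
pca_covariates <- function(geno, n_components = 3) {
  if (!inherits(geno, "geno_matrix")) .fail("`geno` must be a geno_matrix")
  if (anyNA(geno$dosage)) .fail("genotype matrix has missing calls; impute first")
  n_components <- .check_count(n_components, "n_components")
  if (n_components >= min(dim(geno$dosage)))
    .fail("n_components must be < min(lines, markers)")
  pc <- prcomp(geno$dosage, center = TRUE, scale. = FALSE)
  k <- min(n_components, sum(pc$sdev > 1e-8))
  if (k < n_components)
    warning(sprintf("rank-deficient input: returning %d component(s)", k))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  attr(scores, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}
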