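#' Genotype matrix container
#'
#' Bundles a lines x markers dosage matrix with its marker map. Dosage is
#' coded as the count of the alternate allele on a 0--2 scale; fully
#' homozygous doubled-haploid (DH) lines only ever carry 0 or 2 (or `NA`
#' for a missing call). After mean imputation dosages may be fractional.
#'
#' @param dosage numeric matrix, lines in rows, markers in columns. Row and
#'   column names are used as line and marker ids (generated if absent).
#' @param map data.frame with columns `marker`, `chrom`, `pos` (bp,
#'   1-based) and optionally `pos_cm` (genetic position). Rows must match
#'   the columns of `dosage`.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   and `map`.
#' @examples
#' gm <- geno_matrix(matrix(c(0, 2, 2, 0), 2, 2),
#'                   data.frame(marker = c("1_100", "1_200"),
#'                              chrom = c(1, 1), pos = c(100, 200)))
#' dim(gm)
#' @export
geno_matrix <- function(dosage, map) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("L%04d", seq_len(nrow(dosage)))
  if (!all(c("marker", "chrom", "pos") %in% names(map)))
    .fail("map must have columns marker, chrom, pos")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (nrow(map) != ncol(dosage))
    .fail(sprintf("map has %d rows but dosage has %d markers",
                  nrow(map), ncol(dosage)))
  colnames(dosage) <- map$marker
  # positions must be strictly increasing within each chromosome
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      .fail(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  d <- dim(x$dosage)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("geno_matrix: %d lines x %d markers on %d chromosome(s); %.2f%% missing\n",
              d[1], d[2], length(unique(x$map$chrom)), 100 * miss))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  geno_matrix(x$dosage[i, j, drop = FALSE], x$map[j, , drop = FALSE])
}

#' Minor allele frequency per marker
#'
#' Computed on non-missing calls only: the alternate-allele frequency is
#' folded to `min(f, 1 - f)`.
#'
#' @param geno a [geno_matrix].
#' @return Numeric vector, one frequency per marker (NaN for all-missing
#'   markers).
#' @export
maf <- function(geno) {
  f <- colMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Per-marker missing-call rate
#' @param geno a [geno_matrix].
#' @return Numeric vector of missing fractions per marker.
#' @export
missing_rate <- function(geno) colMeans(is.na(geno$dosage))

#' Count heterozygous calls
#'
#' DH lines are fully homozygous; any dosage of 1 is a heterozygous call
#' and indicates either a genotyping error or a non-DH sample.
#'
#' @param geno a [geno_matrix].
#' @return Integer count of calls equal to 1.
#' @export
n_het <- function(geno) sum(geno$dosage == 1, na.rm = TRUE)
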