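# Candidate-gene retrieval: GFF3 gene models and fixed-window interval
# queries around significant SNPs.

#' Load gene models from a GFF3 annotation
#'
#' Parses the file with rtracklayer and keeps `gene`-type features.
#' Coordinates stay 1-based inclusive (GFF3 convention). Gene ids come
#' from the ID/Name/gene_id attribute (first available); a description is
#' taken from the description/Note/product attribute when present.
#'
#' @param path GFF3 file path.
#' @return data.frame of class `gene_set`: gene_id, chrom, start, end,
#'   strand, description.
#' @export
load_gff <- function(path) {
  if (!file.exists(path)) .fail(sprintf("file not found: %s", path))
  # light structural pre-check so parse failures name the offending line
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  if (any(nf != 9))
    .fail(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                  body[which(nf != 9)[1]], nf[nf != 9][1]),
          class = "format_error")
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  genes <- md[!is.na(md$type) & md$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    warning("no gene-type features found in GFF3")
    return(structure(data.frame(gene_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0),
                                description = character(0)),
                     class = c("gene_set", "data.frame")))
  }
  pick <- function(cols) {
    out <- rep(NA_character_, nrow(genes))
    for (cl in cols) if (cl %in% names(genes)) {
      v <- as.character(genes[[cl]])
      out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
    }
    out
  }
  id <- pick(c("ID", "Name", "gene_id"))
  id[is.na(id)] <- paste0("gene", seq_len(nrow(genes)))[is.na(id)]
  desc <- pick(c("description", "Note", "product"))
  structure(data.frame(gene_id = id, chrom = as.character(genes$seqnames),
                       start = genes$start, end = genes$end,
                       strand = as.character(genes$strand),
                       description = ifelse(is.na(desc), "", desc),
                       stringsAsFactors = FALSE),
            class = c("gene_set", "data.frame"))
}

#' Write gene models to GFF3
#'
#' @param genes a `gene_set` data.frame (as from [load_gff]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(nzchar(genes$description),
                         paste0(";description=", genes$description), ""))
  rows <- paste(genes$chrom, "flowerGS", "gene", genes$start, genes$end,
                ".", ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Genes within a fixed window of significant SNPs
#'
#' A gene is a candidate hit for a SNP iff its body [start, end]
#' intersects the closed window [pos - window, pos + window] (so a gene
#' whose nearest edge is exactly `window` bp away is included). Distance
#' is 0 when the SNP lies inside the gene body, otherwise the distance to
#' the nearest gene edge. Strand never affects inclusion; the
#' upstream/downstream relation is purely coordinate-based (gene entirely
#' before the SNP = upstream).
#'
#' @param snps data.frame with columns `snp` (or `marker`), `chrom`,
#'   `pos`; an `assoc_result` works directly (its significant rows are
#'   used).
#' @param genes a `gene_set` data.frame.
#' @param window half-window width in bp (default 10000 = 10 kb each
#'   side).
#' @return data.frame of class `candidate_hits`: snp, trait (if
#'   available), gene_id, chrom, distance, relation
#'   (within/upstream/downstream), description.
#' @export
query_window <- function(snps, genes, window = 10000) {
  if (inherits(snps, "assoc_result")) {
    snps <- data.frame(snp = snps$marker, chrom = snps$chrom, pos = snps$pos,
                       trait = snps$trait,
                       stringsAsFactors = FALSE)[snps$significant, ]
  }
  if (!"snp" %in% names(snps) && "marker" %in% names(snps))
    names(snps)[names(snps) == "marker"] <- "snp"
  if (!all(c("snp", "chrom", "pos") %in% names(snps)))
    .fail("`snps` needs columns snp, chrom, pos")
  if (window < 0) .fail("`window` must be non-negative")
  known <- unique(as.character(genes$chrom))
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    ch <- as.character(snps$chrom[i]); pos <- snps$pos[i]
    if (!ch %in% known) {
      warning(sprintf("SNP %s on unknown chromosome %s skipped",
                      snps$snp[i], ch))
      next
    }
    g <- genes[as.character(genes$chrom) == ch &
                 genes$start <= pos + window & genes$end >= pos - window, ,
               drop = FALSE]
    if (nrow(g) == 0) next
    within <- pos >= g$start & pos <= g$end
    dist <- ifelse(within, 0L, pmin(abs(pos - g$start), abs(pos - g$end)))
    rel <- ifelse(within, "within",
                  ifelse(g$end < pos, "upstream", "downstream"))
    hits[[length(hits) + 1L]] <- data.frame(
      snp = snps$snp[i],
      trait = if ("trait" %in% names(snps)) snps$trait[i] else NA_character_,
      gene_id = g$gene_id, chrom = ch, distance = as.integer(dist),
      relation = rel, description = g$description,
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(snp = character(0), trait = character(0),
               gene_id = character(0), chrom = character(0),
               distance = integer(0), relation = character(0),
               description = character(0))
  rownames(out) <- NULL
  structure(out, class = c("candidate_hits", "data.frame"), window = window)
}
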