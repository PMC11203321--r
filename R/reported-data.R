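# Bundled reference tables for the 379-line multi-parent DH maize
# flowering-time panel: the published variance components per trait and
# the published significant SNP associations from the two multi-locus
# models. Used for in-package consistency checks (heritability
# arithmetic, overlap summaries, candidate-gene windows).

#' Published variance components for the DH flowering-time panel
#'
#' Genotypic, genotype-by-environment, and error variances (days^2) for
#' days to tasseling (DTT), pollen-shedding (DTP), and silking (DTS),
#' with the published entry-mean broad-sense heritability in percent.
#' The trial design had E = 4 environments; R = 2 replicates is the
#' replicate constant under which the entry-mean heritability formula
#' reproduces all three published percentages from these components.
#'
#' @return data.frame: trait, sigma2_g, sigma2_ge, sigma2_e, H2_percent.
#' @export
reported_variance_components <- function() {
  read.table(system.file("extdata", "reported_variance_components.tsv",
                         package = "flowerGS"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Published significant SNP associations
#'
#' The significant SNPs reported for the three flowering-time traits by
#' the two multi-locus GWAS models on the 379-line DH panel, with
#' chromosome, position, bin label, p-value and per-SNP phenotypic
#' variance explained (percent). The second FarmCPU block is labelled
#' DTP (one published table block carries an evident trait-label typo;
#' the cross-trait overlap text fixes the assignment).
#'
#' @return data.frame: model, trait, snp, chrom, pos, bin, p_value,
#'   r2_percent.
#' @export
reported_significant_snps <- function() {
  read.table(system.file("extdata", "reported_significant_snps.tsv",
                         package = "flowerGS"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Path to the bundled synthetic candidate-gene annotation
#'
#' A synthetic GFF3 (coordinates engineered, not the reference genome
#' annotation) placing 24 genes inside the 10 kb windows around the 14
#' reported significant SNP positions -- including one gene whose
#' nearest edge sits exactly 10,000 bp away -- plus decoys just outside
#' the window (10,001 bp) and far from any SNP.
#'
#' @return File path of the GFF3.
#' @export
synthetic_candidate_gff <- function() {
  system.file("extdata", "synthetic_candidate_genes.gff3",
              package = "flowerGS")
}
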