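#' SNP weight panel
#'
#' A `snp_panel` holds per-SNP metadata for genetic risk score construction:
#' the risk allele, its per-allele effect weight on the log-odds scale
#' (summarised from the T2D GWAS literature), the risk-allele frequency, and
#' the population in which the variant was discovered or replicated.
#'
#' @param rsID character vector of unique SNP identifiers.
#' @param risk_allele,other_allele single-base allele labels.
#' @param weight per-allele log-OR effect weights, finite and `>= 0`.
#' @param raf risk-allele frequencies, each strictly inside (0, 1).
#' @param population discovery-population label per SNP (e.g. "East Asian").
#' @param gene optional gene/locus label per SNP.
#' @param chrom,pos optional coordinates.
#' @return a data.frame of class `snp_panel`, one row per SNP.
#' @export
snp_panel <- function(rsID, risk_allele, other_allele, weight, raf,
                      population = "unknown", gene = NA_character_,
                      chrom = NA_character_, pos = NA_integer_) {
  p <- data.frame(rsID = as.character(rsID),
                  risk_allele = as.character(risk_allele),
                  other_allele = as.character(other_allele),
                  weight = as.numeric(weight),
                  raf = as.numeric(raf),
                  population = as.character(population),
                  gene = as.character(gene),
                  chrom = as.character(chrom),
                  pos = as.integer(pos),
                  stringsAsFactors = FALSE)
  validate_panel(p)
}

validate_panel <- function(p) {
  if (nrow(p) < 1) stopf("a SNP panel needs at least one SNP")
  if (anyDuplicated(p$rsID)) stopf("duplicated rsIDs in panel: %s",
                                   paste(unique(p$rsID[duplicated(p$rsID)]), collapse = ", "))
  if (anyNA(p$weight) || any(!is.finite(p$weight)) || any(p$weight < 0)) {
    stopf("panel weights must be finite and >= 0")
  }
  if (anyNA(p$raf) || any(p$raf <= 0) || any(p$raf >= 1)) {
    stopf("invalid panel: risk-allele frequencies must lie strictly in (0, 1)")
  }
  class(p) <- c("snp_panel", "data.frame")
  p
}

#' Packaged synthetic 34-SNP T2D panel
#'
#' Returns the default panel of 34 biallelic T2D-associated common variants.
#' The rsID/gene/population labels of 24 SNPs follow published East Asian and
#' European T2D loci; the remaining 10 SNPs, and *all* effect weights and
#' risk-allele frequencies, are synthetic placeholders (generated once with a
#' fixed seed and frozen), not a reconstruction of any study's panel.
#'
#' @return a `snp_panel` with 34 rows.
#' @export
synthetic_panel_34 <- function() {
  path <- system.file("extdata", "synthetic_panel_34.tsv", package = "gdikit")
  read_panel(path)
}

#' Read / write a SNP panel TSV
#'
#' Tab-separated with header columns `rsID`, `risk_allele`, `other_allele`,
#' `weight`, `raf` and optionally `population`, `gene`, `chrom`, `pos`.
#'
#' @param path file path.
#' @return `read_panel` returns a validated `snp_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("rsID", "risk_allele", "other_allele", "weight", "raf")
  missing <- setdiff(required, names(d))
  if (length(missing)) stopf("panel file %s lacks required columns: %s",
                             path, paste(missing, collapse = ", "))
  for (opt in c("population", "gene", "chrom")) if (is.null(d[[opt]])) d[[opt]] <- NA_character_
  if (is.null(d$pos)) d$pos <- NA_integer_
  validate_panel(d[c(required, "population", "gene", "chrom", "pos")])
}

#' @rdname read_panel
#' @param panel a `snp_panel`.
#' @export
write_panel <- function(panel, path) {
  validate_panel(as.data.frame(panel))
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
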