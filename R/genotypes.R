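# Genotype dosage matrices: subjects x SNPs, additive coding 0/1/2 with NA
# for missing calls. Represented as a plain numeric matrix with subject IDs
# as rownames and rsIDs as colnames, validated against a snp_panel.

#' Validate a genotype dosage matrix against a panel
#'
#' Checks that every non-missing entry is 0, 1 or 2 (fractional dosages are
#' allowed only after mean imputation, controlled by `allow_fractional`) and
#' that the column set is a subset of the panel's rsIDs in panel order.
#'
#' @param genotypes numeric matrix, subjects in rows, rsID colnames.
#' @param panel a `snp_panel`.
#' @param allow_fractional allow imputed non-integer dosages in `[0, 2]`.
#' @return the matrix, invisibly, on success.
#' @export
validate_genotypes <- function(genotypes, panel, allow_fractional = FALSE) {
  if (!is.matrix(genotypes)) stopf("genotypes must be a matrix")
  if (is.null(colnames(genotypes))) stopf("genotype matrix must carry rsID colnames")
  extra <- setdiff(colnames(genotypes), panel$rsID)
  if (length(extra)) stopf("genotype columns not in panel: %s", paste(extra, collapse = ", "))
  keep <- panel$rsID[panel$rsID %in% colnames(genotypes)]
  if (!identical(colnames(genotypes), keep)) {
    stopf("genotype columns must follow panel order")
  }
  v <- genotypes[!is.na(genotypes)]
  if (allow_fractional) {
    if (any(v < 0 | v > 2)) stopf("dosages must lie in [0, 2]")
  } else if (!all(v %in% c(0, 1, 2))) {
    bad <- utils::head(unique(v[!v %in% c(0, 1, 2)]), 3)
    stopf("non-{0,1,2} dosage value(s): %s", paste(bad, collapse = ", "))
  }
  invisible(genotypes)
}

#' Read / write genotype dosage TSVs
#'
#' The dialect is tab-separated, UTF-8, one row per subject: a `subject_id`
#' column followed by one 0/1/2 column per rsID, `NA` for missing calls.
#'
#' @param path file path.
#' @param panel optional `snp_panel`; when supplied the matrix is validated
#'   and aligned against it.
#' @return `read_genotypes` returns a numeric matrix with subject rownames.
#' @export
read_genotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) stopf("genotype file not found: %s", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "subject_id") stopf("genotype file must start with a subject_id column")
  g <- as.matrix(d[-1])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(d$subject_id)
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid dosage at row %d, column %s: %s", bad[1, 1],
          colnames(g)[bad[1, 2]], g[bad[1, , drop = FALSE]])
  }
  if (!is.null(panel)) validate_genotypes(g, panel)
  g
}

#' @rdname read_genotypes
#' @param genotypes dosage matrix as produced by [simulate_genotypes()].
#' @export
write_genotypes <- function(genotypes, path) {
  d <- data.frame(subject_id = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Import a PLINK `.raw` additive dosage file
#'
#' Reads the whitespace-delimited output of `plink --recode A`: header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by `rsID_<countedallele>` columns
#' of 0/1/2 risk-allele counts. Column names are stripped back to rsIDs; the
#' counted allele suffix is checked against the panel's risk allele when a
#' panel is given.
#'
#' @param path path to the `.raw` file.
#' @param panel optional `snp_panel` for alignment and allele checking.
#' @return numeric dosage matrix, IID rownames, rsID colnames.
#' @export
read_plink_raw <- function(path, panel = NULL) {
  if (!file.exists(path)) stopf("raw file not found: %s", path)
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(d))) {
    stopf("not a PLINK .raw file: missing header columns %s",
          paste(setdiff(meta, names(d)), collapse = ", "))
  }
  snpcols <- setdiff(names(d), meta)
  rs <- sub("_[ACGT]$", "", snpcols)
  counted <- sub(".*_", "", snpcols)
  g <- as.matrix(d[snpcols])
  storage.mode(g) <- "double"
  colnames(g) <- rs
  rownames(g) <- as.character(d$IID)
  if (!is.null(panel)) {
    idx <- match(rs, panel$rsID)
    if (anyNA(idx)) stopf("raw file SNPs absent from panel: %s",
                          paste(rs[is.na(idx)], collapse = ", "))
    flip <- counted != panel$risk_allele[idx]
    if (any(flip)) {
      # counted allele is the other allele: reorient to risk-allele dosage
      g[, flip] <- 2 - g[, flip]
    }
    g <- g[, order(idx), drop = FALSE]
    validate_genotypes(g, panel)
  }
  g
}

#' Flag genotype columns inconsistent with their risk-allele frequency
#'
#' A column whose mean dosage differs from `2 * raf` by more than `tol` is a
#' probable allele flip (dosages counted on the wrong allele).
#'
#' @param genotypes dosage matrix aligned to `panel`.
#' @param panel `snp_panel`.
#' @param tol absolute tolerance on the mean-dosage discrepancy.
#' @return character vector of suspect rsIDs (possibly empty).
#' @export
check_allele_orientation <- function(genotypes, panel, tol = 0.5) {
  idx <- match(colnames(genotypes), panel$rsID)
  mu <- colMeans(genotypes, na.rm = TRUE)
  suspects <- colnames(genotypes)[abs(mu - 2 * panel$raf[idx]) > tol]
  suspects
}
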