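# Genetic risk score construction: missingness exclusion, mean-dosage
# imputation, weighted/un-weighted scores, tertile assignment.

#' Flag subjects by genotype missingness
#'
#' Subjects with more than `max_missing` missing SNP genotypes are excluded
#' from all downstream analyses (study rule: "> 2 SNPs missing").
#'
#' @param genotypes dosage matrix (NA = missing call).
#' @param max_missing largest tolerated number of missing genotypes
#'   (default 2).
#' @return list with `included` (logical, named by subject), `n_missing`
#'   (integer per subject) and `n_excluded`.
#' @export
filter_by_missingness <- function(genotypes, max_missing = 2) {
  n_missing <- rowSums(is.na(genotypes))
  included <- n_missing <= max_missing
  list(included = included, n_missing = n_missing,
       n_excluded = sum(!included))
}

#' Impute residual missing dosages by the per-SNP mean
#'
#' Each missing dosage is replaced by that SNP's observed mean dosage in the
#' supplied matrix; a column with no observed calls falls back to the
#' Hardy-Weinberg expectation `2 * raf` from the panel. Non-missing entries
#' are untouched. Run after [filter_by_missingness()], so at most
#' `max_missing` entries per subject are imputed.
#'
#' @param genotypes dosage matrix, possibly with NA.
#' @param panel `snp_panel` aligned to the columns.
#' @return dosage matrix without missing entries (imputed values may be
#'   fractional).
#' @export
impute_missing <- function(genotypes, panel) {
  if (!anyNA(genotypes)) return(genotypes)
  idx <- match(colnames(genotypes), panel$rsID)
  for (j in seq_len(ncol(genotypes))) {
    miss <- is.na(genotypes[, j])
    if (!any(miss)) next
    fill <- if (all(miss)) 2 * panel$raf[idx[j]] else mean(genotypes[!miss, j])
    genotypes[miss, j] <- fill
  }
  genotypes
}

#' Un-weighted genetic risk score
#'
#' Row sum of risk-allele dosages (integer when the matrix is complete;
#' real-valued after mean imputation).
#'
#' @param genotypes complete dosage matrix.
#' @return named numeric score vector.
#' @export
unweighted_grs <- function(genotypes) {
  if (anyNA(genotypes)) stopf("genotypes contain missing values; impute first")
  rowSums(genotypes)
}

#' Weighted genetic risk score
#'
#' Raw score is `sum_j w_j g_j`. With `rescale = TRUE` (default) the score is
#' multiplied by `m / sum(w)` so it lives on the allele-count scale and is
#' directly comparable to the un-weighted score (a weighted score whose mean
#' sits near the un-weighted mean, as in cohorts reporting means ~34.6 vs
#' ~35.9, is only achievable on that scale).
#'
#' @param genotypes complete dosage matrix aligned to `panel`.
#' @param panel `snp_panel` providing the weights.
#' @param rescale rescale to the allele-count scale (default `TRUE`).
#' @return named numeric score vector.
#' @export
weighted_grs <- function(genotypes, panel, rescale = TRUE) {
  if (anyNA(genotypes)) stopf("genotypes contain missing values; impute first")
  idx <- match(colnames(genotypes), panel$rsID)
  if (anyNA(idx)) stopf("genotype columns unaligned with panel: %s",
                        paste(colnames(genotypes)[is.na(idx)], collapse = ", "))
  w <- panel$weight[idx]
  if (sum(w) == 0) stopf("panel weights sum to zero; cannot rescale a weighted score")
  score <- as.numeric(genotypes %*% w)
  if (rescale) score <- score * length(w) / sum(w)
  names(score) <- rownames(genotypes)
  score
}

#' Assign score tertiles
#'
#' Cutpoints are the empirical 1/3 and 2/3 quantiles; a subject with score
#' `<=` the lower cut is tertile 1, `<=` the upper cut tertile 2, else
#' tertile 3. Value-based cutpoints mean tied scores always share a tertile
#' (reproducible and order-independent; with heavy ties the groups can be
#' unequal, degenerating to a single group when all scores coincide).
#'
#' @param scores numeric vector, length `>= 3`.
#' @return list of class `tertile_assignment` with `tertile` (integer 1/2/3
#'   per subject) and `cutpoints` (length-2 numeric).
#' @export
assign_tertiles <- function(scores) {
  if (length(scores) < 3) stopf("need at least 3 subjects to form tertiles")
  cut_lo <- as.numeric(quantile(scores, 1 / 3))
  cut_hi <- as.numeric(quantile(scores, 2 / 3))
  tert <- ifelse(scores <= cut_lo, 1L, ifelse(scores <= cut_hi, 2L, 3L))
  names(tert) <- names(scores)
  structure(list(tertile = tert, cutpoints = c(cut_lo, cut_hi)),
            class = "tertile_assignment")
}

#' Full GRS pipeline
#'
#' filter (`> max_missing` missing excluded) -> impute -> weighted and
#' un-weighted scores -> tertiles, on one call. Idempotent on a complete
#' matrix.
#'
#' @param genotypes dosage matrix, possibly with NA.
#' @param panel `snp_panel`.
#' @param max_missing missingness exclusion threshold (default 2).
#' @param rescale see [weighted_grs()].
#' @return data.frame with one row per *included* subject: `subject_id`,
#'   `weighted_score`, `unweighted_score`, `n_missing`, `tertile`; the
#'   exclusion count and tertile cutpoints are attached as attributes
#'   `n_excluded` and `cutpoints`.
#' @export
grs_pipeline <- function(genotypes, panel, max_missing = 2, rescale = TRUE) {
  flt <- filter_by_missingness(genotypes, max_missing)
  g <- genotypes[flt$included, , drop = FALSE]
  g <- impute_missing(g, panel)
  wsc <- weighted_grs(g, panel, rescale = rescale)
  usc <- unweighted_grs(g)
  tert <- assign_tertiles(wsc)
  out <- data.frame(subject_id = rownames(g),
                    weighted_score = wsc, unweighted_score = usc,
                    n_missing = flt$n_missing[flt$included],
                    tertile = tert$tertile,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- flt$n_excluded
  attr(out, "cutpoints") <- tert$cutpoints
  out
}
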