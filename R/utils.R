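#' Round half away from zero
#'
#' Fixed-point rounding with the "round half up" convention used for the
#' participant-flow percentages (base R `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a per-stage sub-seed from a root seed; keeps all seeds < 2^31.
# Stage order is fixed (genotypes=1, exposure=2, covariates=3, outcomes=4)
# so adding later stages never perturbs earlier draws.
sub_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% 2147483647) + 1000003 * as.numeric(stage)
  as.integer(s %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

assert_prob_vector <- function(p, len = NULL, tol = 1e-12) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stopf("probabilities must be non-negative numbers")
  }
  if (!is.null(len) && length(p) != len) {
    stopf("expected a probability vector of length %d, got %d", len, length(p))
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("probabilities must sum to 1 (got %.15g)", sum(p))
  }
  invisible(p)
}
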