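# GRS construction: missingness rule, imputation, weighted/un-weighted
# scores, tertiles, pipeline idempotence.

test_that("missingness filter applies the > max_missing exclusion rule", {
  panel <- make_panel(5)
  g <- simulate_genotypes(6, panel, seed = 1)
  g[1, 1:3] <- NA  # 3 missing -> excluded
  g[2, 1:2] <- NA  # 2 missing -> retained (boundary)
  flt <- filter_by_missingness(g, max_missing = 2)
  expect_false(flt$included[1])
  expect_true(flt$included[2])
  expect_equal(flt$n_excluded, 1)
  expect_equal(unname(flt$n_missing[1:2]), c(3, 2))
  # flow arithmetic at study scale: 11884 genotyped, 227 with > 2 missing
  expect_equal(11884 - 227, 11657)
})

test_that("mean imputation fills missing dosages and nothing else", {
  panel <- make_panel(3)
  g <- matrix(c(2, 1, 1, 1, 1,
                0, 2, 1, 0, 1,
                NA, NA, NA, NA, NA), ncol = 3,
              dimnames = list(paste0("S", 1:5), panel$rsID[1:3]))
  g2 <- g
  g2[3, 1] <- NA  # remaining observed dosages 2,1,1,1 -> mean 1.25
  out <- impute_missing(g2, panel)
  expect_equal(out[3, 1], mean(c(2, 1, 1, 1)))
  expect_equal(out[, 2], g[, 2])  # untouched column
  expect_equal(unique(out[, 3]), 2 * panel$raf[3])  # fully-missing fallback
  complete <- simulate_genotypes(10, panel, seed = 2)
  expect_identical(impute_missing(complete, panel), complete)
})

test_that("un-weighted and weighted scores follow their formulas", {
  panel <- make_panel(3)
  g <- matrix(c(1, 2, 0), nrow = 1, dimnames = list("S1", panel$rsID))
  expect_equal(unname(unweighted_grs(g)), 3)
  expect_equal(unname(unweighted_grs(matrix(0, 2, 3, dimnames = list(NULL, panel$rsID)))),
               c(0, 0))
  p34 <- make_panel(34)
  g34 <- matrix(2, 1, 34, dimnames = list("S1", p34$rsID))
  expect_equal(unname(unweighted_grs(g34)), 68)

  p2 <- snp_panel(c("rs1", "rs2"), "A", "G", weight = c(0.1, 0.2), raf = c(0.4, 0.6))
  gd <- matrix(c(1, 2), 1, dimnames = list("S1", c("rs1", "rs2")))
  expect_equal(unname(weighted_grs(gd, p2, rescale = FALSE)), 0.5, tolerance = 1e-12)
  expect_equal(unname(weighted_grs(gd, p2, rescale = TRUE)), 0.5 * 2 / 0.3,
               tolerance = 1e-12)
  # equal weights: rescaled weighted score == un-weighted score exactly
  peq <- snp_panel(c("rs1", "rs2", "rs3"), "A", "G", weight = rep(0.17, 3),
                   raf = c(0.3, 0.5, 0.7))
  geq <- simulate_genotypes(50, peq, seed = 3)
  expect_equal(weighted_grs(geq, peq), unweighted_grs(geq), tolerance = 1e-12)
  p0 <- snp_panel("rs1", "A", "G", weight = 0, raf = 0.5)
  expect_error(weighted_grs(matrix(1, 1, 1, dimnames = list("S1", "rs1")), p0),
               "sum to zero")
})

test_that("both scores are strictly monotone in any dosage (positive weights)", {
  panel <- make_panel(6, seed = 11)
  g <- simulate_genotypes(20, panel, seed = 12)
  for (r in 1:5) {
    set.seed(r)
    i <- sample(20, 1); j <- sample(6, 1)
    if (g[i, j] == 2) next
    g2 <- g; g2[i, j] <- g[i, j] + 1
    expect_gt(weighted_grs(g2, panel)[i], weighted_grs(g, panel)[i])
    expect_gt(unweighted_grs(g2)[i], unweighted_grs(g)[i])
  }
})

test_that("tertile assignment: balanced groups, tie degeneracy, near-equal thirds", {
  t9 <- assign_tertiles(1:9)
  expect_equal(unname(t9$tertile), rep(1:3, each = 3))
  tied <- assign_tertiles(rep(5, 10))
  expect_true(all(tied$tertile == 1))
  set.seed(13)
  big <- assign_tertiles(sample(seq_len(11657)))
  sizes <- as.vector(table(big$tertile))
  expect_equal(sum(sizes), 11657)
  expect_true(all(abs(sizes - 11657 / 3) <= 1))
  expect_error(assign_tertiles(c(1, 2)), "at least 3")
})

test_that("filter -> impute -> score pipeline is idempotent on complete data", {
  panel <- make_panel(8, seed = 21)
  g <- simulate_genotypes(120, panel, seed = 22)
  r1 <- grs_pipeline(g, panel)
  r2 <- grs_pipeline(g, panel)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "n_excluded"), 0)
  expect_equal(sum(table(r1$tertile)), nrow(r1))
  # with missingness: excluded subjects carry no scores
  gm <- g
  gm[1, 1:3] <- NA
  rm_ <- grs_pipeline(gm, panel)
  expect_equal(attr(rm_, "n_excluded"), 1)
  expect_false(rownames(g)[1] %in% rm_$subject_id)
})

test_that("allele-orientation check flags flipped dosage columns", {
  # a flip moves the mean dosage from 2p to 2(1-p): detectable when |4p-2| > 0.5
  panel <- snp_panel(paste0("rs", 1:3), "A", "G", weight = rep(0.1, 3),
                     raf = c(0.5, 0.15, 0.7))
  g <- simulate_genotypes(3000, panel, seed = 32)
  expect_length(check_allele_orientation(g, panel), 0)
  g[, 2] <- 2 - g[, 2]  # flip the p = 0.15 column
  flagged <- check_allele_orientation(g, panel)
  expect_true("rs2" %in% flagged)
})
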