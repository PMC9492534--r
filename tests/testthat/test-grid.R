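test_that("covariance standardization handles exact, boundary and invalid input", {
  expect_equal(standardize_correlation(0.32, 0.64, 0.64), 0.5)
  expect_equal(standardize_correlation(0, 0.3, 2.1), 0)
  expect_equal(standardize_correlation(-0.2, 0.4, 0.1), -1)
  expect_warning(r <- standardize_correlation(1 + 1e-9, 1, 1), "clipped")
  expect_equal(r, 1)
  expect_error(standardize_correlation(1.1, 1, 1), "invalid covariance")
  expect_error(standardize_correlation(0.1, 0, 1), "positive")
})

test_that("phenotypic correlation decomposition follows the path identity", {
  expect_equal(
    decompose_phenotypic_correlation(sqrt(0.6), sqrt(0.6), 0, 0,
                                     sqrt(0.4), sqrt(0.4),
                                     rA = 0.8, rC = 0, rE = 0.25),
    0.58)
  a <- sqrt(0.5); c <- sqrt(0.3); e <- sqrt(0.2)
  expect_equal(
    decompose_phenotypic_correlation(a, a, c, c, e, e, 1, 1, 1), 1)
  expect_equal(
    decompose_phenotypic_correlation(a, a, c, c, e, e, 0, 0, 0), 0)
  expect_error(
    decompose_phenotypic_correlation(0.9, 0.9, 0.5, 0.5, 0.5, 0.5, 0.8),
    "standardized")
})

test_that("grid cell counting follows the age combinatorics", {
  panel <- small_panel()
  grid <- run_grid(panel, "logBMI", ages = c(3, 8), ci_method = "none")
  s <- attr(grid, "grid_summary")
  expect_equal(s$n_cells, 1L)
  expect_equal(nrow(grid), 2L)                   # one row per sex
  expect_equal(sum(!is.na(grid$r_A)), 2L)        # one coefficient per sex
  expect_error(run_grid(panel, "logBMI", ages = 3), "at least two ages")
  expect_error(run_grid(panel, "logBMI", ages = c(15, 17)),
               "do not intersect")
})

test_that("model-implied trait correlation equals its path decomposition per cell", {
  panel <- small_panel()
  grid <- run_grid(panel, "logBMI", ages = c(3, 8), ci_method = "wald")
  conv <- grid[!is.na(grid$converged) & grid$converged, ]
  expect_gt(nrow(conv), 0)
  for (i in seq_len(nrow(conv))) {
    r <- conv[i, ]
    rhs <- decompose_phenotypic_correlation(
      r$a1, r$a2, r$c1, r$c2, r$e1, r$e2,
      rA = r$r_A, rC = ifelse(is.na(r$r_C), 0, r$r_C), rE = r$r_E)
    expect_lt(abs(r$r_trait - rhs), 1e-8)
  }
  expect_true(all(is.finite(conv$r_A_lo)))
  expect_true(all(conv$r_A_lo <= conv$r_A & conv$r_A <= conv$r_A_hi))
})

test_that("grid output is invariant to input row order", {
  set.seed(77)
  panel <- small_panel()
  shuffled <- panel[sample(nrow(panel)), ]
  class(shuffled) <- class(panel)
  g1 <- run_grid(panel, "logBMI", ages = c(3, 8), ci_method = "none")
  g2 <- run_grid(shuffled, "logBMI", ages = c(3, 8), ci_method = "none")
  expect_equal(as.data.frame(g1), as.data.frame(g2), tolerance = 1e-12)
})

test_that("cells below the pair minimum are skipped, not fabricated", {
  panel <- small_panel()
  grid <- run_grid(panel, "logBMI", ages = c(3, 8), min_pairs = 10^6,
                   ci_method = "none")
  s <- attr(grid, "grid_summary")
  expect_equal(s$n_skipped, 1L)
  expect_true(all(grid$skipped))
  expect_true(all(is.na(grid$r_A)))
})

test_that("matrix serialization puts males above and females below the diagonal", {
  panel <- small_panel()
  grid <- run_grid(panel, "logBMI", ages = c(3, 8), ci_method = "none")
  M <- grid_matrix(grid, "r_A")
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(M[1, 2], grid$r_A[grid$sex == "M"])
  expect_equal(M[2, 1], grid$r_A[grid$sex == "F"])
  expect_true(all(is.na(diag(M))))
})
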