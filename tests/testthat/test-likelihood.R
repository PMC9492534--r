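test_that("standard-normal mode value is exact", {
  # identity expected covariance, zero mean, observation at the mode
  p <- cholesky_paths(A = matrix(0, 2, 2), E = diag(2))
  pd <- manual_pair_data(matrix(0, 1, 4), "MZM")
  ll <- pair_loglikelihood(pd, p)
  expect_equal(as.numeric(ll), -(4 / 2) * log(2 * pi), tolerance = 1e-12)
  expect_equal(attr(ll, "n_jittered"), 0L)
})

test_that("log-likelihood is additive over independent families", {
  set.seed(5)
  p <- cholesky_paths(A = matrix(c(0.8, 0.3, 0, 0.6), 2),
                      C = matrix(c(0.4, 0.2, 0, 0.3), 2),
                      E = matrix(c(0.5, 0.1, 0, 0.5), 2))
  y <- matrix(rnorm(8), 2, 4)
  both <- pair_loglikelihood(manual_pair_data(y, c("MZM", "DZF")), p)
  one <- pair_loglikelihood(manual_pair_data(y[1, , drop = FALSE], "MZM"), p)
  two <- pair_loglikelihood(manual_pair_data(y[2, , drop = FALSE], "DZF"), p)
  expect_equal(as.numeric(both), as.numeric(one) + as.numeric(two),
               tolerance = 1e-12)
})

test_that("FIML matches the explicit determinant-and-inverse oracle with missingness", {
  set.seed(123)
  n <- 50
  groups <- sample(c("MZM", "MZF", "DZM", "DZF", "OSDZ"), n, replace = TRUE)
  y <- matrix(rnorm(n * 4), n, 4)
  # random masks, keeping at least one observation per twin
  for (i in seq_len(n)) {
    for (tw in 0:1) {
      drop <- sample(0:1, 1)
      if (drop) y[i, tw * 2 + sample(1:2, 1)] <- NA
    }
  }
  mkL <- function(v) matrix(c(v[1], v[2], 0, v[3]), 2)
  p <- cholesky_paths(
    A = list(M = mkL(c(0.9, 0.4, 0.7)), F = mkL(c(0.8, 0.2, 0.75))),
    C = list(M = mkL(c(0.5, -0.2, 0.4)), F = mkL(c(0.45, 0.1, 0.35))),
    E = list(M = mkL(c(0.6, 0.1, 0.5)), F = mkL(c(0.65, 0.0, 0.55))),
    rg_os = 0.8,
    means = list(M = cbind(MZ = c(0.1, -0.1), DZ = c(0.2, 0.0)),
                 F = cbind(MZ = c(0.0, 0.05), DZ = c(-0.1, 0.15))))
  pd <- manual_pair_data(y, groups)
  ll <- pair_loglikelihood(pd, p)

  gset <- unique(groups)
  gc <- lapply(gset, function(g) expected_pair_covariance(p, g))
  gm <- lapply(gset, function(g) twinace:::pair_mean_vector(p, g))
  names(gc) <- names(gm) <- gset
  oracle <- brute_force_loglik(y, gc, gm, groups)
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-8)
})

test_that("analytic score equals the finite-difference gradient", {
  pd <- small_pd()
  stats <- twinace:::pair_suff_stats(pd)
  set.seed(2)
  for (mt in c("AE", "ACE")) {
    for (dg in c("single_sex", "five_group")) {
      ms <- twinace:::make_mspec(2L, mt, dg)
      obj <- twinace:::make_objective(
        stats, twinace:::group_structs(ms, unique(pd$group)), ms)
      th <- twinace:::moment_start(pd, ms) + rnorm(ms$n_par, 0, 0.01)
      ga <- obj$gr(th)
      gn <- twinace:::num_grad(obj$fn, th)
      expect_lt(max(abs(ga - gn)) / max(1, max(abs(ga))), 1e-5)
    }
  }
})

test_that("a singular observed submatrix is jittered and counted", {
  # A + E with E = 0 makes the pair covariance singular (MZ correlation 1)
  p <- cholesky_paths(A = matrix(1, 1, 1), E = matrix(0, 1, 1))
  pd <- manual_pair_data(matrix(c(0.3, 0.3), 1, 2), "MZM")
  ll <- pair_loglikelihood(pd, p)
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(attr(ll, "n_jittered"), 1L)
})
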