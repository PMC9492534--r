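test_that("univariate expected covariances reproduce the ACE correlation structure", {
  p <- cholesky_paths(A = sqrt(0.6), C = sqrt(0.2), E = sqrt(0.2))
  expect_equal(expected_pair_covariance(p, "MZM"),
               matrix(c(1, 0.8, 0.8, 1), 2))
  expect_equal(expected_pair_covariance(p, "DZF"),
               matrix(c(1, 0.5, 0.5, 1), 2))
})

test_that("bivariate Cholesky cross-blocks carry the genetic correlation", {
  LA <- matrix(c(1, 0.5, 0, sqrt(0.75)), 2)
  p <- cholesky_paths(A = LA, E = matrix(0, 2, 2))
  S <- expected_pair_covariance(p, "MZM")
  expect_equal(S[1, 4], 0.5)            # twin1 var1 x twin2 var2
  VA <- LA %*% t(LA)
  expect_equal(standardize_correlation(VA[1, 2], VA[1, 1], VA[2, 2]), 0.5)
})

test_that("OSDZ with rg_os = 1 and equal paths reduces to the SSDZ matrix", {
  LA <- matrix(c(0.7, 0.3, 0, 0.6), 2)
  LE <- matrix(c(0.5, 0.1, 0, 0.4), 2)
  p <- cholesky_paths(A = LA, E = LE, C = NULL, rg_os = 1)
  expect_equal(expected_pair_covariance(p, "OSDZ"),
               expected_pair_covariance(p, "DZM"))
  # and rg_os < 1 attenuates only the genetic cross-twin block
  p2 <- cholesky_paths(A = LA, E = LE, rg_os = 0.5)
  S1 <- expected_pair_covariance(p2, "DZM")
  S2 <- expected_pair_covariance(p2, "OSDZ")
  expect_equal(S2[1:2, 1:2], S1[1:2, 1:2])
  expect_equal(S2[1:2, 3:4], 0.5 * S1[1:2, 3:4])
})

test_that("expected pair covariances are symmetric positive semidefinite", {
  set.seed(17)
  for (i in 1:20) {
    mk <- function() {
      L <- matrix(0, 2, 2)
      L[lower.tri(L, diag = TRUE)] <- rnorm(3)
      L
    }
    p <- cholesky_paths(A = list(M = mk(), F = mk()),
                        C = list(M = mk(), F = mk()),
                        E = list(M = mk(), F = mk()),
                        rg_os = runif(1))
    for (g in c("MZM", "MZF", "DZM", "DZF", "OSDZ")) {
      S <- expected_pair_covariance(p, g)
      expect_lt(max(abs(S - t(S))), 1e-12)
      expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
    }
  }
})
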