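test_that("BMI formula and its scale consistency", {
  expect_equal(compute_bmi(60, 150), 60 / 1.5^2)
  expect_equal(compute_bmi(50, 200), 12.5)
  for (w in c(3.5, 20, 80)) expect_equal(compute_bmi(w, 100), w)

  set.seed(1)
  w <- runif(20, 10, 90); h <- runif(20, 70, 190)
  expect_equal(compute_bmi(2 * w, h), 2 * compute_bmi(w, h))
  s <- 1.3
  expect_equal(compute_bmi(w, s * h), compute_bmi(w, h) / s^2)

  expect_error(compute_bmi(-1, 150), "weight_kg")
  expect_error(compute_bmi(60, 0), "height_cm")
  expect_error(compute_bmi(NaN, 150), "weight_kg")
})

test_that("log-normalization symmetrizes a log-normal sample", {
  # symmetric logs: skewness exactly zero
  expect_equal(log_normalize(exp(c(1, 2, 3)))$skewness_after, 0)
  # degenerate sample: 0 by convention
  expect_equal(sample_skewness(rep(5, 10)), 0)
  expect_error(log_normalize(c(1, -2)), "positive")

  # log-normal(0, 0.5): closed-form natural-scale skewness
  # (e^{s2} + 2) sqrt(e^{s2} - 1) with s2 = 0.25 is about 1.75
  set.seed(42)
  x <- rlnorm(10000, 0, 0.5)
  ln <- log_normalize(x)
  expect_gt(ln$skewness_before, 1)
  expect_lt(abs(ln$skewness_before - 1.75), 0.5)  # heavy-tailed, slow MC
  expect_lt(abs(ln$skewness_after), 0.1)
  expect_equal(ln$log_values, log(x))
})

test_that("stratum residualization matches the normal-equations oracle", {
  set.seed(7)
  n <- 200
  exact_age <- runif(n, 6.5, 7.5)
  birth_year <- sample(1985:2005, n, replace = TRUE)
  cohort <- sample(c("a", "b", "c"), n, replace = TRUE)
  y <- 2 + 0.3 * exact_age - 0.01 * birth_year +
    c(a = 0, b = 0.5, c = -0.2)[cohort] + rnorm(n)

  r <- residualize_stratum(y, exact_age, birth_year, cohort)

  X <- cbind(1, exact_age, birth_year,
             as.numeric(cohort == "b"), as.numeric(cohort == "c"))
  beta <- solve(t(X) %*% X, t(X) %*% y)     # explicit normal equations
  expect_lt(max(abs(r - (y - X %*% beta))), 1e-8)

  # orthogonality to every standardized regressor
  for (j in 2:ncol(X))
    expect_lt(abs(sum(r * scale(X[, j]))), 1e-6)
  expect_lt(abs(mean(r)), 1e-10)

  # idempotence
  r2 <- residualize_stratum(r, exact_age, birth_year, cohort)
  expect_lt(max(abs(r2 - r)), 1e-10)
})

test_that("degenerate designs fall back deterministically", {
  y <- c(3, 5, 9, 1)
  # all covariates constant: both collinear columns dropped, intercept-only
  w <- capture_warnings(
    r <- residualize_stratum(y, rep(7, 4), rep(1990, 4), rep("a", 4)))
  expect_true(length(w) >= 1 && all(grepl("collinear", w)))
  expect_equal(r, y - mean(y), ignore_attr = TRUE)

  # perfect linear fit in exact age
  age <- c(6.6, 6.9, 7.2, 7.4)
  r <- residualize_stratum(10 + 2 * age, age, c(1990, 1991, 1990, 1991),
                           rep("a", 4))
  expect_lt(max(abs(r)), 1e-10)

  # stratum smaller than the parameter count: centred values
  expect_warning(
    r <- residualize_stratum(c(1, 2), c(6.5, 7.5), c(1990, 1991), c("a", "b")),
    "centred")
  expect_equal(r, c(-0.5, 0.5), ignore_attr = TRUE)
})

test_that("panel residuals are stratum-centred and uniquely sourced", {
  panel <- small_panel()
  strata <- split(panel$value, list(panel$trait, panel$age, panel$sex), drop = TRUE)
  for (s in strata) expect_lt(abs(mean(s)), 1e-8)
  expect_false(any(duplicated(
    panel[, c("trait", "family_id", "twin_index", "age")])))
})

test_that("age binning keeps the record closest to the bin centre", {
  coh <- data.frame(
    family_id = "F1", twin_index = 1L, zygosity_group = "MZM", sex = "M",
    age_years = 8L, exact_age = c(7.6, 8.1, 8.4), height_cm = c(120, 130, 140),
    weight_kg = 30, birth_year = 1990L, cohort = "a")
  coh2 <- coh; coh2$twin_index <- 2L; coh2$height_cm <- c(121, 131, 141)
  panel <- suppressWarnings(build_panel(rbind(coh, coh2), traits = "height"))
  h8 <- panel[panel$age == 8, ]
  expect_equal(nrow(h8), 2L)   # one per twin, the exact_age 8.1 record
  # residual difference preserves the raw difference of the kept records
  expect_equal(diff(h8$value), 131 - 130 - 0, tolerance = 1e-10)
})
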