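test_that("config validation rejects malformed generative inputs", {
  bad_R <- matrix(c(1, 1.5, 1.5, 1), 2)  # symmetric, unit diagonal, indefinite
  expect_error(
    twin_sim_config(ages = c(3, 8), traits = list(
      height = plain_height_spec(R_A = bad_R))),
    "R_A for trait 'height' is not positive semidefinite")
  expect_error(
    twin_sim_config(ages = c(3, 8), traits = list(
      height = trait_spec(a2 = 0.5, c2 = 0.2, e2 = 0.2, log_normal = FALSE))),
    "sum to 1")
  expect_error(twin_sim_config(zygosity_mix = c(MZ = 0.5, SSDZ = 0.3, OSDZ = 0.3)),
               "sum to 1")
  expect_error(twin_sim_config(rg_os = 1.2), "rg_os")
  expect_error(twin_sim_config(n_pairs_per_group = c(MZM = -1, MZF = 1, DZM = 1,
                                                     DZF = 1, OSDZ = 1)),
               ">= 0")
})

test_that("identical seed and config give a byte-identical record stream", {
  cfg <- twin_sim_config(ages = c(3, 8), n_pairs = 150, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- twin_sim_config(ages = c(3, 8), n_pairs = 150, seed = 100)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("simulated records satisfy the twin-pair structural invariants", {
  cfg <- twin_sim_config(ages = c(5L, 9L), n_pairs = 400, seed = 3,
                         missingness_rate = 0)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$height_cm > 0))
  expect_true(all(coh$weight_kg > 0))
  per_fam <- split(coh, coh$family_id)
  expect_true(all(vapply(per_fam, function(d)
    setequal(unique(d$twin_index), 1:2), TRUE)))
  os <- coh[coh$zygosity_group == "OSDZ", ]
  expect_true(all(vapply(split(os, os$family_id), function(d)
    setequal(unique(d$sex), c("M", "F")), TRUE)))
  mz <- coh[coh$zygosity_group %in% c("MZM", "MZF"), ]
  expect_true(all(vapply(split(mz, mz$family_id), function(d)
    length(unique(d$sex)) == 1L, TRUE)))
})

test_that("no familial components means no co-twin correlation", {
  cfg <- twin_sim_config(
    ages = 8L, n_pairs = 6000, seed = 5, missingness_rate = 0,
    traits = list(height = plain_height_spec(a2 = 0, c2 = 0, e2 = 1)))
  coh <- simulate_cohort(cfg)
  wide <- reshape(coh[, c("family_id", "twin_index", "height_cm", "zygosity_group")],
                  idvar = c("family_id", "zygosity_group"),
                  timevar = "twin_index", direction = "wide")
  for (g in c("MZM", "MZF", "DZM", "DZF", "OSDZ")) {
    w <- wide[wide$zygosity_group == g, ]
    r <- double_entry_cor(w$height_cm.1, w$height_cm.2)
    expect_lt(abs(r), 3 / sqrt(nrow(w)))
  }
})

test_that("MZ intraclass correlation matches the generating a2 + c2", {
  cfg <- twin_sim_config(
    ages = 8L,
    n_pairs_per_group = c(MZM = 20000, MZF = 0, DZM = 0, DZF = 0, OSDZ = 0),
    traits = list(
      bmi = trait_spec(a2 = 0.6, c2 = 0.2, e2 = 0.2, dz_mean_offset = 0,
                       cohort_effects = c(coh = 0), birth_year_slope = 0,
                       log_normal = TRUE),
      height = plain_height_spec()),
    missingness_rate = 0, seed = 21)
  coh <- simulate_cohort(cfg)
  lb <- log(compute_bmi(coh$weight_kg, coh$height_cm))
  w1 <- lb[coh$twin_index == 1][order(coh$family_id[coh$twin_index == 1])]
  w2 <- lb[coh$twin_index == 2][order(coh$family_id[coh$twin_index == 2])]
  expect_lt(abs(double_entry_cor(w1, w2) - 0.8), 0.02)
})

test_that("per-age variances and cross-twin/cross-age moments match the config", {
  R_A <- cor_decay(0.9, c(3, 8, 13))
  R_C <- cor_decay(0.8, c(3, 8, 13))
  cfg <- twin_sim_config(
    ages = c(3L, 8L, 13L),
    n_pairs_per_group = c(MZM = 10000, MZF = 0, DZM = 10000, DZF = 0, OSDZ = 0),
    traits = list(height = plain_height_spec(a2 = 0.6, c2 = 0.2, e2 = 0.2,
                                             R_A = R_A, R_C = R_C, R_E = 0.3)),
    missingness_rate = 0, seed = 31)
  coh <- simulate_cohort(cfg, return_latents = TRUE)
  lat <- attr(coh, "latents")

  # within-person cross-age correlation of the A part reproduces R_A
  A_mz <- lat$MZM$height$A[, 1:3]
  emp <- cor(A_mz)
  expect_lt(max(abs(emp - R_A)), 0.04)

  # DZ cross-twin covariance of the summed latent is 0.5 a2 R_A + c2 R_C
  P_dz <- lat$DZM$height$A + lat$DZM$height$C + lat$DZM$height$E
  cross <- cov(P_dz[, 1:3], P_dz[, 4:6])
  cross <- (cross + t(cross)) / 2
  expect_lt(max(abs(cross - (0.5 * 0.6 * R_A + 0.2 * R_C))), 0.04)

  # equal total variances in MZ and DZ, and close to the calibrated SD
  cal <- default_growth_reference()
  for (age in c(3, 8, 13)) {
    v_mz <- var(coh$height_cm[coh$zygosity_group == "MZM" & coh$age_years == age])
    v_dz <- var(coh$height_cm[coh$zygosity_group == "DZM" & coh$age_years == age])
    v_target <- cal$height_sd[cal$age == age & cal$sex == "M"]^2
    expect_lt(abs(v_mz / v_target - 1), 0.05)
    expect_lt(abs(v_dz / v_target - 1), 0.05)
  }
})

test_that("missingness thins records at the configured per-age rate", {
  cfg <- twin_sim_config(ages = c(3L, 8L), n_pairs = 4000, seed = 8,
                         missingness_rate = c(0.5, 0.1))
  coh <- simulate_cohort(cfg)
  n_fam <- length(unique(coh$family_id))
  p3 <- nrow(coh[coh$age_years == 3, ]) / (2 * n_fam)
  p8 <- nrow(coh[coh$age_years == 8, ]) / (2 * n_fam)
  expect_lt(abs(p3 - 0.5), 0.03)
  expect_lt(abs(p8 - 0.9), 0.03)
})
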