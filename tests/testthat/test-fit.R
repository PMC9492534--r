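test_that("single-sex AE fit recovers generating values on balanced data", {
  cfg <- twin_sim_config(
    ages = c(7L, 12L),
    n_pairs_per_group = c(MZM = 1500, MZF = 0, DZM = 1500, DZF = 0, OSDZ = 0),
    traits = list(height = plain_height_spec(
      a2 = 0.6, c2 = 0, e2 = 0.4,
      R_A = matrix(c(1, 0.8, 0.8, 1), 2),
      R_C = diag(2), R_E = matrix(c(1, 0.2, 0.2, 1), 2))),
    missingness_rate = 0, seed = 41)
  panel <- suppressWarnings(build_panel(simulate_cohort(cfg), traits = "height"))
  pd <- pair_data(panel, "height", c(7, 12))
  fit <- fit_model(pd, model_tag = "AE", design = "single_sex")
  expect_true(fit$converged)
  sm <- fit$summary
  expect_lt(abs(sm$A1 - 0.6), 0.06)
  expect_lt(abs(sm$A2 - 0.6), 0.06)
  expect_lt(abs(sm$rA - 0.8), 0.06)
  expect_lt(abs(sm$rE - 0.2), 0.08)
  # standardized shares sum to one per variable
  expect_equal(sm$A1 + sm$C1 + sm$E1, 1, tolerance = 1e-8)
  expect_equal(sm$A2 + sm$C2 + sm$E2, 1, tolerance = 1e-8)
})

test_that("ACE log-likelihood dominates nested AE on the same data", {
  pd <- small_pd()
  fit_ae <- small_fit()
  fit_ace <- fit_model(pd, model_tag = "ACE", design = "five_group")
  expect_gte(fit_ace$logL, fit_ae$logL - 1e-6)
})

test_that("fits are deterministic and sign-fixed", {
  pd <- small_pd()
  f1 <- fit_model(pd, "AE", "five_group")
  f2 <- fit_model(pd, "AE", "five_group")
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-10)
  for (s in names(f1$paths))
    for (L in f1$paths[[s]])
      expect_true(all(diag(L) >= 0))
})

test_that("row order of the input panel does not change the fit", {
  panel <- small_panel()
  shuffled <- panel[sample(nrow(panel)), ]
  class(shuffled) <- class(panel)
  pd1 <- pair_data(panel, "logBMI", c(3, 8))
  pd2 <- pair_data(shuffled, "logBMI", c(3, 8))
  expect_identical(pd1$y, pd2$y)
  expect_identical(pd1$group, pd2$group)
})

test_that("underidentified or incomplete designs are rejected", {
  panel <- small_panel()
  # only MZ groups: no MZ/DZ contrast
  mz_only <- panel[panel$zygosity_group %in% c("MZM", "MZF"), ]
  class(mz_only) <- class(panel)
  expect_error(fit_model(pair_data(mz_only, "logBMI", c(3, 8)), "AE", "single_sex"),
               "MZ and DZ")
  # five_group without OSDZ
  no_os <- panel[panel$zygosity_group != "OSDZ", ]
  class(no_os) <- class(panel)
  expect_error(fit_model(pair_data(no_os, "logBMI", c(3, 8)), "AE", "five_group"),
               "five zygosity groups")
  # fewer pairs than parameters (4 families per group = 20 < 27 free params)
  keep_ids <- unlist(lapply(split(panel$family_id, panel$zygosity_group),
                            function(x) unique(x)[1:4]))
  few <- panel[panel$family_id %in% keep_ids, ]
  class(few) <- class(panel)
  expect_error(fit_model(pair_data(few, "logBMI", c(3, 8)), "ACE", "five_group"),
               "free parameters")
})

test_that("co-twins missing at both ages are dropped from pair data", {
  panel <- small_panel()
  pd <- pair_data(panel, "logBMI", c(3, 8))
  # every retained family has both twins partially observed
  t1 <- rowSums(!is.na(pd$y[, 1:2, drop = FALSE]))
  t2 <- rowSums(!is.na(pd$y[, 3:4, drop = FALSE]))
  expect_true(all(t1 >= 1 & t2 >= 1))
  expect_gte(pd$n_dropped, 0)
})
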