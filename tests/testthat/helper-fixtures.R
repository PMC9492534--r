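# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# a clean height-only trait with no nuisance signal (for recovery tests)
plain_height_spec <- function(a2 = 0.6, c2 = 0.2, e2 = 0.2,
                              R_A = 0.95, R_C = 0.9, R_E = 0.3) {
  trait_spec(a2 = a2, c2 = c2, e2 = e2, R_A = R_A, R_C = R_C, R_E = R_E,
             dz_mean_offset = 0, cohort_effects = c(coh = 0),
             birth_year_slope = 0, log_normal = FALSE)
}

# balanced two-age cohort with known bivariate truth, five groups
recovery_config <- function(n_per_group, seed, a2 = 0.6, c2 = 0.2, e2 = 0.2,
                            rA = 0.8, rC = 0.5, rE = 0.2,
                            ages = c(7L, 12L), missingness = 0) {
  R2 <- function(r) matrix(c(1, r, r, 1), 2)
  twin_sim_config(
    ages = ages,
    n_pairs_per_group = c(MZM = n_per_group, MZF = n_per_group,
                          DZM = n_per_group, DZF = n_per_group,
                          OSDZ = n_per_group),
    traits = list(height = plain_height_spec(a2, c2, e2,
                                             R_A = R2(rA), R_C = R2(rC),
                                             R_E = R2(rE))),
    missingness_rate = missingness,
    seed = seed)
}

recovery_panel <- function(n_per_group, seed, ...) {
  suppressWarnings(build_panel(
    simulate_cohort(recovery_config(n_per_group, seed, ...)),
    traits = "height"))
}

# small mixed panel with both traits and missingness, memoised
small_panel <- function() memo("small_panel", {
  cfg <- twin_sim_config(ages = c(3L, 8L), n_pairs = 600,
                         missingness_rate = 0.1, seed = 11)
  suppressWarnings(build_panel(simulate_cohort(cfg)))
})

small_pd <- function() memo("small_pd", pair_data(small_panel(), "logBMI", c(3, 8)))

small_fit <- function() memo("small_fit",
  fit_model(small_pd(), model_tag = "AE", design = "five_group"))

# hand-constructed paired data (bypasses pair_data) for likelihood tests
manual_pair_data <- function(y, group) {
  structure(list(y = y, group = group,
                 family_id = sprintf("F%03d", seq_len(nrow(y))),
                 ages = if (ncol(y) == 4L) c(1L, 2L) else 1L,
                 trait = "height", n_var = ncol(y) / 2L,
                 n_families = nrow(y), n_dropped = 0L),
            class = "paired_age_data")
}

# brute-force MVN log-density from explicit determinant and inverse
brute_force_loglik <- function(y, group_cov, group_mu, groups) {
  ll <- 0
  for (i in seq_len(nrow(y))) {
    obs <- which(!is.na(y[i, ]))
    S <- group_cov[[groups[i]]][obs, obs, drop = FALSE]
    mu <- group_mu[[groups[i]]][obs]
    x <- y[i, obs] - mu
    ll <- ll - 0.5 * (length(obs) * log(2 * pi) + log(det(S)) +
                        drop(t(x) %*% solve(S) %*% x))
  }
  ll
}
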