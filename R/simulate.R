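# Synthetic twin-cohort generator.  Latent structure per trait:
#   P = A + C + E on a standardized scale (unit variance per age), with
#   cross-age correlation matrices R_A, R_C, R_E, cross-twin correlation
#   1 / 0.5 / 0.5*rg_os for A (MZ / SSDZ / OSDZ), 1 for C, 0 for E.
# The standardized latent is then placed on the measurement scale via the
# per-age/sex calibration (log scale for log-normal traits), so MZ and DZ
# total variances are equal by construction.

spectral_sqrt <- function(S) {
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(es$values, 0)   # tolerate numerically semi-definite input
  es$vectors %*% (sqrt(vals) * t(es$vectors))
}

# pair covariance of one latent component over both twins' age vectors:
#   [ D1 R D1 ,  k D1 R D2 ]
#   [ k D2 R D1, D2 R D2   ]
component_pair_cov <- function(R, sd1, sd2, k) {
  S11 <- outer(sd1, sd1) * R
  S22 <- outer(sd2, sd2) * R
  S12 <- k * outer(sd1, sd2) * R
  rbind(cbind(S11, S12), cbind(t(S12), S22))
}

group_sexes <- function(group) {
  switch(group,
         MZM = c("M", "M"), MZF = c("F", "F"),
         DZM = c("M", "M"), DZF = c("F", "F"),
         OSDZ = c("M", "F"),
         stop("unknown zygosity group: ", group))
}

group_kA <- function(group, rg_os) {
  switch(group, MZM = 1, MZF = 1, DZM = 0.5, DZF = 0.5, OSDZ = 0.5 * rg_os)
}

is_dz_group <- function(group) group %in% c("DZM", "DZF", "OSDZ")

#' Simulate a longitudinal twin cohort
#'
#' Draws a seeded cohort of twin pairs with the latent A/C/E structure,
#' zygosity mix, calibration moments, zygosity mean shifts, nuisance
#' cohort/birth-year effects and per-age missingness specified in `config`.
#' Output is long-format: one row per twin per measured age.
#'
#' BMI-like (log-normal) traits are generated on the log scale, shifted and
#' scaled to the per-age/sex calibration moments, exponentiated, and
#' converted to weight given the simulated height, so the returned table
#' carries `height_cm` and `weight_kg` like a raw anthropometric extract.
#'
#' @param config a [twin_sim_config()].
#' @param return_latents logical; attach the latent component draws as
#'   attribute `"latents"` (a list per zygosity group and trait with the
#'   `A`, `C`, `E` matrices, columns = twin1 ages then twin2 ages). Used for
#'   debugging and calibration checks.
#' @return data.frame with columns `family_id`, `twin_index`,
#'   `zygosity_group`, `sex`, `age_years`, `exact_age`, `height_cm`,
#'   `weight_kg`, `birth_year`, `cohort`. Identical config and seed give a
#'   byte-identical table.
#' @examples
#' cfg <- twin_sim_config(ages = c(3, 8), n_pairs = 100, seed = 7)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config, return_latents = FALSE) {
  stopifnot(inherits(config, "twin_sim_config"))
  set.seed(config$seed)
  ages <- config$ages
  m <- length(ages)
  groups <- names(config$n_pairs_per_group)
  trait_names <- names(config$traits)
  if (!"height" %in% trait_names)
    stop("config must include a 'height' trait (needed to derive weight)")
  has_bmi <- "bmi" %in% trait_names

  fam_offset <- 0L
  out <- vector("list", length(groups))
  latents <- list()

  for (g in groups) {
    n <- config$n_pairs_per_group[[g]]
    if (n == 0L) next
    sexes <- group_sexes(g)
    kA <- group_kA(g, config$rg_os)

    family_id <- sprintf("F%06d", fam_offset + seq_len(n))
    fam_offset <- fam_offset + n
    birth_year <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                         n, replace = TRUE)
    cohort_labels <- names(config$traits[[1]]$cohort_effects)
    cohort <- sample(cohort_labels, n, replace = TRUE)
    # for OSDZ, which twin_index the male twin carries
    male_index <- if (g == "OSDZ") sample(1:2, n, replace = TRUE) else rep(1L, n)

    trait_vals <- list()   # per trait: n x 2m measurement-scale matrix
    lat_g <- list()
    for (tr in trait_names) {
      sp <- config$traits[[tr]]
      lat <- matrix(0, n, 2 * m)
      lat_comp <- list()
      for (comp in c("A", "C", "E")) {
        R <- sp[[paste0("R_", comp)]]
        share_col <- c(A = "a2", C = "c2", E = "e2")[[comp]]
        sd1 <- sqrt(sp$shares[, share_col, sexes[1]])
        sd2 <- sqrt(sp$shares[, share_col, sexes[2]])
        k <- switch(comp, A = kA, C = 1, E = 0)
        S <- component_pair_cov(R, sd1, sd2, k)
        Z <- matrix(stats::rnorm(n * 2 * m), n, 2 * m)
        draw <- Z %*% spectral_sqrt(S)
        lat <- lat + draw
        lat_comp[[comp]] <- draw
      }
      if (return_latents) lat_g[[tr]] <- lat_comp

      # place on measurement scale per twin/age
      vals <- matrix(NA_real_, n, 2 * m)
      for (tw in 1:2) {
        s <- sexes[tw]
        cal <- sp$calibration[sp$calibration$sex == s, ]
        cal <- cal[order(cal$age), ]
        for (j in seq_len(m)) {
          col <- (tw - 1) * m + j
          z <- lat[, col]
          row <- match(ages[j], cal$age)
          mu_nat <- cal$mean[row]
          sd_nat <- cal$sd[row]
          shift <- sp$cohort_effects[cohort] +
            sp$birth_year_slope * (birth_year - 1995) +
            if (is_dz_group(g)) sp$dz_mean_offset else 0
          if (sp$log_normal) {
            lp <- lognormal_params(mu_nat, sd_nat)
            vals[, col] <- exp(lp$meanlog + shift + lp$sdlog * z)
          } else {
            vals[, col] <- mu_nat + shift + sd_nat * z
          }
        }
      }
      trait_vals[[tr]] <- vals
    }
    if (return_latents) latents[[g]] <- lat_g

    # exact ages: per twin per age, jitter within the 1-year bin
    exact <- matrix(rep(ages, each = n, times = 2), n, 2 * m) +
      matrix(stats::runif(n * 2 * m, -0.45, 0.45), n, 2 * m)

    keep <- matrix(stats::runif(n * 2 * m), n, 2 * m) >=
      rep(rep(config$missingness_rate, each = n), times = 2)

    height <- trait_vals[["height"]]
    bmi <- if (has_bmi) trait_vals[["bmi"]] else NULL

    rows <- vector("list", 2L)
    for (tw in 1:2) {
      cols <- (tw - 1) * m + seq_len(m)
      idx <- which(keep[, cols, drop = FALSE], arr.ind = TRUE)  # (family, age)
      if (nrow(idx) == 0L) next
      fam <- idx[, 1]; aj <- idx[, 2]
      cc <- cols[aj]
      h <- height[cbind(fam, cc)]
      w <- if (has_bmi) bmi[cbind(fam, cc)] * (h / 100)^2 else NA_real_
      tw_index <- if (g == "OSDZ") {
        ifelse(male_index[fam] == 1L, tw, 3L - tw)
      } else rep(tw, length(fam))
      sex_tw <- sexes[tw]
      rows[[tw]] <- data.frame(
        family_id = family_id[fam],
        twin_index = as.integer(tw_index),
        zygosity_group = g,
        sex = sex_tw,
        age_years = ages[aj],
        exact_age = exact[cbind(fam, cc)],
        height_cm = h,
        weight_kg = w,
        birth_year = birth_year[fam],
        cohort = cohort[fam],
        stringsAsFactors = FALSE)
    }
    out[[match(g, groups)]] <- do.call(rbind, rows)
  }

  res <- do.call(rbind, out)
  res <- res[order(res$family_id, res$twin_index, res$age_years), ]
  rownames(res) <- NULL
  if (return_latents) attr(res, "latents") <- latents
  res
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data.frame from [simulate_cohort()] (or same layout).
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(family_id = "character", cohort = "character"))
}
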