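#' Body mass index
#'
#' `weight_kg / (height_cm / 100)^2`, in kg/m^2. Vectorized.
#'
#' @param weight_kg positive finite weight in kilograms.
#' @param height_cm positive finite height in centimetres.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(60, 150)   # 26.67
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("weight_kg must be positive and finite")
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("height_cm must be positive and finite")
  weight_kg / (height_cm / 100)^2
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`.
#' A zero-variance (or n < 3) sample has skewness 0 by convention, so
#' degenerate strata propagate no NaN.
#'
#' @param x numeric vector.
#' @return scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) return(0)
  g1 <- mean(xc^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Log-transform a positive sample and report skewness before/after
#'
#' Natural-log normalization as used for BMI, which is right-skewed on the
#' natural scale and close to normal on the log scale.
#'
#' @param values positive numeric vector.
#' @return list with `log_values`, `skewness_before`, `skewness_after`.
#' @examples
#' log_normalize(rlnorm(100, 2.8, 0.15))
#' @export
log_normalize <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite for log-normalization")
  lv <- log(values)
  list(log_values = lv,
       skewness_before = sample_skewness(values),
       skewness_after = sample_skewness(lv))
}

#' Residualize one age-sex stratum on exact age, birth year and cohort
#'
#' Ordinary least-squares residuals of `values` on
#' `[1, exact_age, birth_year, cohort indicators]`, computed within a
#' single 1-year-age-by-sex stratum. Rank-deficient designs drop columns
#' deterministically from the right (cohort indicators first, then birth
#' year, then exact age) with a warning. A stratum with fewer observations
#' than design columns falls back to centring, with a warning.
#'
#' @param values numeric response within the stratum.
#' @param exact_age numeric exact ages.
#' @param birth_year integer birth years.
#' @param cohort cohort labels (entered as indicator contrasts).
#' @return numeric residuals (mean zero).
#' @export
residualize_stratum <- function(values, exact_age, birth_year, cohort) {
  n <- length(values)
  stopifnot(length(exact_age) == n, length(birth_year) == n, length(cohort) == n)
  if (n < 2L) stop("a stratum needs at least 2 observations")

  cohort <- as.factor(cohort)
  X <- cbind(`(Intercept)` = 1, exact_age = exact_age, birth_year = birth_year)
  if (nlevels(cohort) > 1L) {
    D <- stats::model.matrix(~ cohort)[, -1, drop = FALSE]
    X <- cbind(X, D)
  }

  if (n < ncol(X)) {
    warning("stratum smaller than design; falling back to centred values")
    return(values - mean(values))
  }
  # drop collinear columns from the right until full rank
  repeat {
    q <- qr(X)
    if (q$rank == ncol(X)) break
    warning(sprintf("dropping collinear design column '%s'",
                    colnames(X)[ncol(X)]))
    X <- X[, -ncol(X), drop = FALSE]
  }
  stats::lm.fit(X, values)$residuals
}

bin_age <- function(exact_age) pmin(pmax(round(exact_age), 1L), 19L)

#' Build the analysis-ready phenotype panel
#'
#' Turns a raw cohort table (one row per twin per measurement) into
#' residualized phenotypes per trait, age bin and sex: BMI is computed from
#' weight and height, log-transformed, and both log-BMI and raw height are
#' residualized on exact age, birth year and cohort within each
#' 1-year-age-by-sex stratum.
#'
#' A measurement at exact age x is assigned to bin `round(x)` clipped to
#' [1, 19]; if a twin has several measures in one bin the one closest to
#' the bin centre is kept (ties: first record).
#'
#' @param cohort data.frame in the layout of [simulate_cohort()].
#' @param traits character subset of `c("bmi", "height")`.
#' @return data.frame of class `phenotype_panel` with columns `family_id`,
#'   `twin_index`, `zygosity_group`, `sex`, `age`, `trait`, `value`
#'   (residual) and `n_stratum`.
#' @export
build_panel <- function(cohort, traits = c("bmi", "height")) {
  traits <- match.arg(traits, several.ok = TRUE)
  need <- c("family_id", "twin_index", "zygosity_group", "sex",
            "exact_age", "height_cm", "weight_kg", "birth_year", "cohort")
  if (!all(need %in% names(cohort)))
    stop("cohort is missing columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "))

  d <- cohort
  d$age <- bin_age(d$exact_age)
  # one record per (twin, bin): closest to bin centre, ties -> first
  d$.dist <- abs(d$exact_age - d$age)
  d$.ord <- seq_len(nrow(d))
  d <- d[order(d$family_id, d$twin_index, d$age, d$.dist, d$.ord), ]
  dup <- duplicated(d[, c("family_id", "twin_index", "age")])
  d <- d[!dup, ]

  panels <- list()
  for (tr in traits) {
    if (tr == "bmi") {
      ok <- is.finite(d$weight_kg) & is.finite(d$height_cm) &
        d$weight_kg > 0 & d$height_cm > 0
      dd <- d[ok, ]
      dd$.y <- log(compute_bmi(dd$weight_kg, dd$height_cm))
    } else {
      ok <- is.finite(d$height_cm) & d$height_cm > 0
      dd <- d[ok, ]
      dd$.y <- dd$height_cm
    }
    strata <- split(seq_len(nrow(dd)), list(age = dd$age, sex = dd$sex),
                    drop = TRUE)
    res <- numeric(nrow(dd))
    nstr <- integer(nrow(dd))
    for (ix in strata) {
      if (length(ix) < 2L) {
        res[ix] <- 0
        nstr[ix] <- length(ix)
        next
      }
      res[ix] <- residualize_stratum(dd$.y[ix], dd$exact_age[ix],
                                     dd$birth_year[ix], dd$cohort[ix])
      nstr[ix] <- length(ix)
    }
    panels[[tr]] <- data.frame(
      family_id = dd$family_id, twin_index = dd$twin_index,
      zygosity_group = dd$zygosity_group, sex = dd$sex, age = dd$age,
      trait = if (tr == "bmi") "logBMI" else "height",
      value = res, n_stratum = nstr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, panels)
  out <- out[order(out$trait, out$family_id, out$twin_index, out$age), ]
  rownames(out) <- NULL
  class(out) <- c("phenotype_panel", "data.frame")
  out
}

#' @rdname build_panel
#' @param panel a `phenotype_panel`.
#' @param path file path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname build_panel
#' @export
read_panel_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(family_id = "character"))
  class(out) <- c("phenotype_panel", "data.frame")
  out
}
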