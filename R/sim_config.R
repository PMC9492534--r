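#' Cross-age correlation matrix with geometric decay
#'
#' Convenience constructor for the latent cross-age correlation matrices of
#' [trait_spec()]: entry (j, k) is `rho^|age_j - age_k|`.
#'
#' @param rho decay per year of age gap, in `[0, 1]`.
#' @param ages integer vector of ages the matrix indexes.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
cor_decay <- function(rho, ages) {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0, rho <= 1)
  outer(ages, ages, function(j, k) rho^abs(j - k))
}

# expand a2/c2/e2 given as scalar, per-age vector, or list(M=, F=) into an
# ages x 3 x 2 array (dims: age, component, sex)
expand_shares <- function(a2, c2, e2, ages) {
  m <- length(ages)
  one_sex <- function(a, c, e) {
    v <- cbind(rep_len(a, m), rep_len(c, m), rep_len(e, m))
    colnames(v) <- c("a2", "c2", "e2")
    v
  }
  get_sex <- function(x, s) if (is.list(x)) x[[s]] else x
  arr <- array(NA_real_, dim = c(m, 3, 2),
               dimnames = list(NULL, c("a2", "c2", "e2"), c("M", "F")))
  for (s in c("M", "F"))
    arr[, , s] <- one_sex(get_sex(a2, s), get_sex(c2, s), get_sex(e2, s))
  arr
}

resolve_cor <- function(x, ages, label, trait) {
  if (is.matrix(x)) {
    R <- x
  } else {
    R <- cor_decay(x, ages)
  }
  m <- length(ages)
  if (!all(dim(R) == c(m, m)))
    stop(sprintf("%s for trait '%s' must be %dx%d", label, trait, m, m))
  if (max(abs(R - t(R))) > 1e-10)
    stop(sprintf("%s for trait '%s' is not symmetric", label, trait))
  if (max(abs(diag(R) - 1)) > 1e-10)
    stop(sprintf("%s for trait '%s' does not have a unit diagonal", label, trait))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("%s for trait '%s' is not positive semidefinite (min eigenvalue %.3g)",
                 label, trait, min(ev)))
  R
}

#' Per-trait generative specification for the synthetic cohort
#'
#' Defines, for one phenotype, the standardized variance-component shares,
#' the cross-age correlation structure of each latent component, the
#' zygosity mean shift, nuisance covariate effects and the moment
#' calibration used to place the latent scale onto measurement units.
#'
#' @param a2,c2,e2 standardized additive-genetic, shared-environment and
#'   unique-environment variance shares; each a scalar, a per-age vector, or
#'   a `list(M = , F = )` of either. Must sum to 1 at every age/sex.
#' @param R_A,R_C,R_E cross-age correlation matrices of the latent A, C and
#'   E components: either a full symmetric PSD matrix over `ages`, or a
#'   scalar decay rate passed to [cor_decay()].
#' @param dz_mean_offset additive mean shift of DZ relative to MZ twins, on
#'   the generated scale (log scale for a log-normal trait, measurement
#'   units otherwise).
#' @param cohort_effects named numeric vector of additive cohort offsets
#'   (same scale as `dz_mean_offset`); the names are the cohort labels.
#' @param birth_year_slope additive linear birth-year effect per year
#'   (centred at 1995), same scale.
#' @param log_normal logical: generate the trait log-normally (latent scale
#'   is the natural-log scale) or normally.
#' @param calibration data.frame with columns `age`, `sex`, `mean`, `sd`
#'   giving per-age/sex natural-scale moments. Defaults are filled from
#'   [default_growth_reference()] by [twin_sim_config()] when `NULL`.
#' @return object of class `trait_spec` (a list).
#' @export
trait_spec <- function(a2 = 0.6, c2 = 0.2, e2 = 0.2,
                       R_A = 0.95, R_C = 0.9, R_E = 0.3,
                       dz_mean_offset = 0,
                       cohort_effects = c(cohA = 0, cohB = 0, cohC = 0),
                       birth_year_slope = 0,
                       log_normal = TRUE,
                       calibration = NULL) {
  structure(list(a2 = a2, c2 = c2, e2 = e2,
                 R_A = R_A, R_C = R_C, R_E = R_E,
                 dz_mean_offset = dz_mean_offset,
                 cohort_effects = cohort_effects,
                 birth_year_slope = birth_year_slope,
                 log_normal = log_normal,
                 calibration = calibration),
            class = "trait_spec")
}

default_trait_specs <- function() {
  list(
    bmi = trait_spec(a2 = 0.6, c2 = 0.2, e2 = 0.2,
                     R_A = 0.95, R_C = 0.9, R_E = 0.3,
                     dz_mean_offset = 0.01,
                     cohort_effects = c(cohA = 0, cohB = 0.02, cohC = -0.02),
                     birth_year_slope = 0.002,
                     log_normal = TRUE),
    height = trait_spec(a2 = 0.8, c2 = 0.1, e2 = 0.1,
                        R_A = 0.95, R_C = 0.9, R_E = 0.3,
                        dz_mean_offset = 0.5,
                        cohort_effects = c(cohA = 0, cohB = 0.5, cohC = -0.5),
                        birth_year_slope = 0.05,
                        log_normal = FALSE)
  )
}

default_calibration <- function(trait) {
  ref <- default_growth_reference()
  if (trait == "bmi") {
    data.frame(age = ref$age, sex = ref$sex, mean = ref$bmi_mean, sd = ref$bmi_sd)
  } else if (trait == "height") {
    data.frame(age = ref$age, sex = ref$sex, mean = ref$height_mean, sd = ref$height_sd)
  } else {
    # unitless default for ad-hoc traits
    data.frame(age = rep(1:19, 2), sex = rep(c("M", "F"), each = 19),
               mean = 0, sd = 1)
  }
}

#' Configuration of the synthetic twin-cohort generator
#'
#' Assembles and validates everything [simulate_cohort()] needs: the age
#' grid, pair counts per zygosity group (or a total split by the zygosity
#' mix), per-trait generative specs, the opposite-sex genetic scaling, the
#' per-age missingness and the seed.
#'
#' @param ages integer ages (years) at which each twin is measured.
#' @param n_pairs total number of complete pairs, split across groups by
#'   `zygosity_mix` (MZ and SSDZ halves split equally by sex). Ignored when
#'   `n_pairs_per_group` is given.
#' @param zygosity_mix named proportions `c(MZ = , SSDZ = , OSDZ = )`
#'   summing to 1.
#' @param n_pairs_per_group optional named counts for
#'   `MZM, MZF, DZM, DZF, OSDZ` (non-negative integers).
#' @param traits named list of [trait_spec()] objects.
#' @param rg_os opposite-sex additive-genetic scaling in `[0, 1]`: the OSDZ
#'   cross-twin genetic correlation is `0.5 * rg_os`.
#' @param missingness_rate probability that a (twin, age) measurement is
#'   absent; scalar or per-age vector.
#' @param birth_year_range integer range families' birth years are drawn
#'   from (uniformly).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config including the seed.
#' @return object of class `twin_sim_config`.
#' @examples
#' cfg <- twin_sim_config(ages = c(3, 8), n_pairs = 200, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
twin_sim_config <- function(ages = 1:19,
                            n_pairs = 2000,
                            zygosity_mix = c(MZ = 0.38, SSDZ = 0.33, OSDZ = 0.29),
                            n_pairs_per_group = NULL,
                            traits = default_trait_specs(),
                            rg_os = 1,
                            missingness_rate = 0.2,
                            birth_year_range = c(1980, 2010),
                            seed = 1) {
  ages <- as.integer(ages)
  if (length(ages) < 1L || anyDuplicated(ages) || any(ages < 1L) || any(ages > 19L))
    stop("ages must be distinct integers in [1, 19]")
  ages <- sort(ages)

  if (is.null(n_pairs_per_group)) {
    if (abs(sum(zygosity_mix) - 1) > 1e-8)
      stop("zygosity_mix proportions must sum to 1")
    if (any(zygosity_mix < 0)) stop("zygosity_mix proportions must be non-negative")
    n_pairs_per_group <- c(
      MZM = round(n_pairs * zygosity_mix[["MZ"]] / 2),
      MZF = round(n_pairs * zygosity_mix[["MZ"]] / 2),
      DZM = round(n_pairs * zygosity_mix[["SSDZ"]] / 2),
      DZF = round(n_pairs * zygosity_mix[["SSDZ"]] / 2),
      OSDZ = round(n_pairs * zygosity_mix[["OSDZ"]]))
  }
  need <- c("MZM", "MZF", "DZM", "DZF", "OSDZ")
  if (!all(need %in% names(n_pairs_per_group)))
    stop("n_pairs_per_group must name MZM, MZF, DZM, DZF, OSDZ")
  n_pairs_per_group <- n_pairs_per_group[need]
  if (any(n_pairs_per_group < 0)) stop("pair counts must be >= 0")

  if (!is.numeric(rg_os) || rg_os < 0 || rg_os > 1)
    stop("rg_os must lie in [0, 1]")

  miss <- rep_len(missingness_rate, length(ages))
  if (any(miss < 0) || any(miss > 1))
    stop("missingness_rate must lie in [0, 1]")

  if (is.null(names(traits)) || any(names(traits) == ""))
    stop("traits must be a named list of trait_spec objects")

  resolved <- list()
  for (tr in names(traits)) {
    sp <- traits[[tr]]
    if (!inherits(sp, "trait_spec")) stop(sprintf("traits$%s is not a trait_spec", tr))
    shares <- expand_shares(sp$a2, sp$c2, sp$e2, ages)
    if (any(shares < 0) || any(shares > 1))
      stop(sprintf("component shares for trait '%s' must lie in [0, 1]", tr))
    tot <- apply(shares, c(1, 3), sum)
    if (max(abs(tot - 1)) > 1e-12)
      stop(sprintf("component shares for trait '%s' must sum to 1 at every age/sex", tr))
    sp$shares <- shares
    sp$R_A <- resolve_cor(sp$R_A, ages, "R_A", tr)
    sp$R_C <- resolve_cor(sp$R_C, ages, "R_C", tr)
    sp$R_E <- resolve_cor(sp$R_E, ages, "R_E", tr)
    if (is.null(sp$calibration)) sp$calibration <- default_calibration(tr)
    cal <- sp$calibration
    if (!all(c("age", "sex", "mean", "sd") %in% names(cal)))
      stop(sprintf("calibration for trait '%s' needs columns age, sex, mean, sd", tr))
    if (!all(ages %in% cal$age[cal$sex == "M"]) ||
        !all(ages %in% cal$age[cal$sex == "F"]))
      stop(sprintf("calibration for trait '%s' does not cover all requested ages", tr))
    resolved[[tr]] <- sp
  }

  structure(list(ages = ages,
                 n_pairs_per_group = n_pairs_per_group,
                 traits = resolved,
                 rg_os = rg_os,
                 missingness_rate = miss,
                 birth_year_range = as.integer(birth_year_range),
                 seed = as.integer(seed)),
            class = "twin_sim_config")
}

#' @export
print.twin_sim_config <- function(x, ...) {
  cat("twin_sim_config\n")
  cat("  ages:", paste(x$ages, collapse = " "), "\n")
  cat("  pairs:", paste(sprintf("%s=%d", names(x$n_pairs_per_group),
                                x$n_pairs_per_group), collapse = " "), "\n")
  cat("  traits:", paste(names(x$traits), collapse = ", "), "\n")
  cat("  rg_os:", x$rg_os, " seed:", x$seed, "\n")
  invisible(x)
}
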