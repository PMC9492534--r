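# Descriptive calibration table: per-age, per-sex sample sizes and means/SDs
# of BMI (kg/m^2) and height (cm) in a pooled longitudinal twin database,
# ages 1-19.  Used as the default moment targets of the synthetic generator.

.growth_ref_males <- matrix(c(
  # age      n   bmi_mean bmi_sd height_mean height_sd
   1,  14860, 17.1, 1.40,  73.9, 4.43,
   2,  12379, 16.5, 1.41,  86.8, 4.31,
   3,  14835, 15.9, 1.42,  96.1, 4.40,
   4,   7633, 15.8, 1.69, 102.5, 4.89,
   5,   6603, 15.2, 1.43, 111.4, 5.91,
   6,   2233, 15.4, 1.52, 114.1, 5.61,
   7,  11856, 15.4, 1.77, 124.4, 6.50,
   8,   5217, 15.7, 1.79, 128.3, 6.38,
   9,   5149, 16.4, 2.33, 133.8, 6.78,
  10,   9687, 16.6, 2.34, 141.0, 7.15,
  11,   7177, 17.3, 2.65, 144.4, 7.09,
  12,   9831, 17.8, 2.82, 151.9, 7.98,
  13,   3474, 18.4, 2.90, 158.4, 8.94,
  14,   7250, 19.5, 3.07, 165.7, 8.84,
  15,   3270, 19.9, 3.20, 172.1, 8.42,
  16,   5540, 20.7, 2.89, 175.7, 7.39,
  17,   6125, 21.2, 2.86, 177.8, 7.12,
  18,   3692, 21.7, 2.98, 178.8, 7.28,
  19,   2901, 22.0, 2.87, 179.3, 7.29), ncol = 6, byrow = TRUE)

.growth_ref_females <- matrix(c(
   1,  14978, 16.8, 1.42,  72.5, 4.47,
   2,  12134, 16.2, 1.42,  85.6, 4.36,
   3,  15279, 15.7, 1.48,  95.1, 4.50,
   4,   7737, 15.7, 1.81, 101.3, 4.86,
   5,   6564, 15.1, 1.54, 110.7, 6.05,
   6,   2065, 15.3, 1.60, 113.2, 5.57,
   7,  12305, 15.4, 1.98, 123.5, 6.50,
   8,   5192, 15.7, 2.03, 127.6, 6.40,
   9,   5120, 16.5, 2.62, 133.0, 6.97,
  10,   9940, 16.7, 2.62, 140.6, 7.30,
  11,   7357, 17.5, 2.83, 144.8, 7.47,
  12,  10161, 18.0, 2.93, 153.0, 8.06,
  13,   3413, 18.7, 3.11, 158.0, 7.49,
  14,   7800, 19.8, 3.19, 162.1, 6.79,
  15,   3266, 20.2, 3.23, 164.7, 7.11,
  16,   6350, 20.7, 3.01, 164.9, 6.50,
  17,   6904, 20.7, 2.80, 165.7, 6.54,
  18,   3960, 21.3, 3.34, 165.8, 6.71,
  19,   3529, 21.4, 3.29, 166.1, 6.71), ncol = 6, byrow = TRUE)

#' Default growth calibration table
#'
#' Per-age (1-19), per-sex sample sizes, means and standard deviations of BMI
#' (kg/m^2) and height (cm) from a pooled multi-cohort longitudinal twin
#' database. These moments are the default calibration of
#' [simulate_cohort()]: simulated BMI is log-normal with the tabulated
#' natural-scale mean/SD (moment-matched on the log scale) and simulated
#' height is normal with the tabulated mean/SD.
#'
#' @return A data.frame with columns `age`, `sex` (`"M"`/`"F"`), `n`,
#'   `bmi_mean`, `bmi_sd`, `height_mean`, `height_sd`.
#' @examples
#' head(default_growth_reference())
#' @export
default_growth_reference <- function() {
  cols <- c("age", "n", "bmi_mean", "bmi_sd", "height_mean", "height_sd")
  m <- as.data.frame(.growth_ref_males)
  f <- as.data.frame(.growth_ref_females)
  names(m) <- names(f) <- cols
  m$sex <- "M"
  f$sex <- "F"
  out <- rbind(m, f)
  out[, c("age", "sex", "n", "bmi_mean", "bmi_sd", "height_mean", "height_sd")]
}

# log-normal moment matching: natural-scale mean m, sd s -> (meanlog, sdlog)
lognormal_params <- function(m, s) {
  s2log <- log1p((s / m)^2)
  list(meanlog = log(m) - s2log / 2, sdlog = sqrt(s2log))
}
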