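# Method-of-moments estimators under the classical co-twin correlation
# structure (A: 1 in MZ / 0.5 in DZ; C: 1 in both; E: 0), used for
# optimizer starting values and as independent oracles for the ML engine.

#' Falconer variance-component estimates from twin correlations
#'
#' Inverts rMZ = a2 + c2, rDZ = a2/2 + c2:
#' `a2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`.
#' Raw values may fall outside `[0, 1]`; they are returned alongside
#' 0-truncated versions and a truncation flag, never rejected.
#'
#' @param r_MZ,r_DZ intraclass correlations in `[-1, 1]`.
#' @return list with `a2`, `c2`, `e2` (raw), `a2_trunc`, `c2_trunc`,
#'   `e2_trunc` (clamped at 0, renormalized to sum 1) and `truncated`.
#' @examples
#' falconer_estimates(0.8, 0.5)   # a2 = 0.6, c2 = 0.2, e2 = 0.2
#' @export
falconer_estimates <- function(r_MZ, r_DZ) {
  stopifnot(abs(r_MZ) <= 1, abs(r_DZ) <= 1)
  a2 <- 2 * (r_MZ - r_DZ)
  c2 <- 2 * r_DZ - r_MZ
  e2 <- 1 - r_MZ
  raw <- c(a2 = a2, c2 = c2, e2 = e2)
  truncated <- any(raw < 0)
  tr <- pmax(raw, 0)
  tr <- tr / sum(tr)
  list(a2 = a2, c2 = c2, e2 = e2,
       a2_trunc = tr[["a2"]], c2_trunc = tr[["c2"]], e2_trunc = tr[["e2"]],
       truncated = truncated)
}

#' Moment decomposition of a cross-twin cross-age covariance
#'
#' Solves covMZ = covA + covC, covDZ = covA/2 + covC, within-person
#' covP = covA + covC + covE for the component covariances:
#' `covA = 2 (covMZ - covDZ)`, `covC = 2 covDZ - covMZ`,
#' `covE = covP - covMZ`.
#'
#' @param covMZ_ct,covDZ_ct cross-twin cross-age covariances in MZ and DZ
#'   pairs.
#' @param covP_wp within-person cross-age covariance.
#' @return list with `covA`, `covC`, `covE`.
#' @examples
#' moment_bivariate(0.48, 0.30, 0.58)   # covA 0.36, covC 0.12, covE 0.10
#' @export
moment_bivariate <- function(covMZ_ct, covDZ_ct, covP_wp) {
  stopifnot(is.finite(covMZ_ct), is.finite(covDZ_ct), is.finite(covP_wp))
  list(covA = 2 * (covMZ_ct - covDZ_ct),
       covC = 2 * covDZ_ct - covMZ_ct,
       covE = covP_wp - covMZ_ct)
}

#' Double-entry twin-pair statistics
#'
#' Pearson correlation (or covariance) between co-twins with each pair
#' entered in both orders, which removes the arbitrariness of twin ordering
#' and equals the usual intraclass estimator up to O(1/n).
#'
#' @param x1,y2 first twin's and second twin's values (`double_entry_cor`),
#'   or the four columns of a cross-trait/cross-age block
#'   (`double_entry_cov`). NA pairs are dropped.
#' @return scalar correlation / covariance.
#' @export
double_entry_cor <- function(x1, y2) {
  ok <- is.finite(x1) & is.finite(y2)
  x1 <- x1[ok]; y2 <- y2[ok]
  if (length(x1) < 2L) return(NA_real_)
  u <- c(x1, y2)
  v <- c(y2, x1)
  stats::cor(u, v)
}

#' @rdname double_entry_cor
#' @param x2,y1 co-twin columns completing the cross block: the returned
#'   covariance is of twin A's `x` with co-twin B's `y`, double-entered.
#' @export
double_entry_cov <- function(x1, y2, x2, y1) {
  ok1 <- is.finite(x1) & is.finite(y2)
  ok2 <- is.finite(x2) & is.finite(y1)
  u <- c(x1[ok1], x2[ok2])
  v <- c(y2[ok1], y1[ok2])
  if (length(u) < 2L) return(NA_real_)
  stats::cov(u, v)
}
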