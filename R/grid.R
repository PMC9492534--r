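# Age-by-age correlation grids: one bivariate Cholesky fit per unordered
# age pair, per-sex genetic / environmental / trait correlations, and the
# square-matrix serialization (upper triangle males, lower triangle
# females).

#' Standardize a component covariance into a correlation
#'
#' `cov_X / sqrt(V_X1 * V_X2)`. Values outside `[-1, 1]` by less than
#' 1e-8 (rounding) are clipped with a warning; larger excursions signal an
#' invalid decomposition and are rejected.
#'
#' @param cov_X component covariance between the two variables.
#' @param V_X1,V_X2 positive component variances.
#' @return correlation in `[-1, 1]`.
#' @examples
#' standardize_correlation(0.32, 0.64, 0.64)   # 0.5
#' @export
standardize_correlation <- function(cov_X, V_X1, V_X2) {
  if (!(V_X1 > 0) || !(V_X2 > 0)) stop("component variances must be positive")
  r <- cov_X / sqrt(V_X1 * V_X2)
  if (abs(r) > 1) {
    if (abs(r) - 1 < 1e-8) {
      warning(sprintf("correlation %.12f clipped to [-1, 1]", r))
      r <- sign(r)
    } else {
      stop(sprintf("standardized correlation %.6f outside [-1, 1]: invalid covariance decomposition", r))
    }
  }
  r
}

#' Decompose a phenotypic correlation into its A/C/E contributions
#'
#' The model identity
#' `r(P1, P2) = a1 * rA * a2 + c1 * rC * c2 + e1 * rE * e2`,
#' where `a`, `c`, `e` are the square roots of the standardized variance
#' components of each variable (so `a_i^2 + c_i^2 + e_i^2 = 1`).
#'
#' @param a1,a2,c1,c2,e1,e2 standardized paths per variable.
#' @param rA,rC,rE component correlations.
#' @return the implied phenotypic correlation.
#' @examples
#' decompose_phenotypic_correlation(sqrt(0.6), sqrt(0.6), 0, 0,
#'                                  sqrt(0.4), sqrt(0.4),
#'                                  rA = 0.8, rC = 0, rE = 0.25)  # 0.58
#' @export
decompose_phenotypic_correlation <- function(a1, a2, c1, c2, e1, e2,
                                             rA, rC = 0, rE = 0) {
  for (tot in list(c(a1, c1, e1), c(a2, c2, e2))) {
    if (abs(sum(tot^2) - 1) > 1e-8)
      stop("paths must be standardized: a^2 + c^2 + e^2 = 1 per variable")
  }
  a1 * rA * a2 + c1 * rC * c2 + e1 * rE * e2
}

grid_sexes <- function(design) if (design == "five_group") c("M", "F") else "all"

cell_row <- function(trait, model_tag, sex, j, k) {
  data.frame(trait = trait, model = model_tag, sex = sex,
             age_j = j, age_k = k, n_pairs = NA_integer_,
             converged = NA, skipped = TRUE,
             r_trait = NA_real_, r_A = NA_real_, r_C = NA_real_,
             r_E = NA_real_,
             r_A_lo = NA_real_, r_A_hi = NA_real_,
             r_E_lo = NA_real_, r_E_hi = NA_real_,
             a1 = NA_real_, a2 = NA_real_, c1 = NA_real_, c2 = NA_real_,
             e1 = NA_real_, e2 = NA_real_,
             stringsAsFactors = FALSE)
}

#' Fit the bivariate model over every age pair
#'
#' Runs one bivariate Cholesky fit per unordered age pair (j < k) of the
#' requested ages and collects, per sex, the trait correlation and the
#' additive genetic / shared environmental / unique environmental
#' correlations with confidence intervals. Cells with fewer jointly
#' informative pairs than `min_pairs` (or, for the five-group design,
#' missing zygosity groups) are reported as skipped rather than dropped.
#'
#' @param panel a `phenotype_panel`.
#' @param trait panel trait name (`"logBMI"` or `"height"`).
#' @param ages integer ages to cross; at least two must be present in the
#'   panel.
#' @param model_tag `"AE"` (default, main model) or `"ACE"`.
#' @param design `"five_group"` (default; sex-specific paths, free OSDZ
#'   genetic scaling) or `"single_sex"`.
#' @param min_pairs minimum retained families per cell (default 30).
#' @param ci_method `"wald"` (default; tractable over a full grid),
#'   `"profile"`, or `"none"`.
#' @param level confidence level for the intervals.
#' @return data.frame of class `correlation_grid`, one row per (sex, age
#'   pair), with attribute `grid_summary` = list(n_cells, n_converged,
#'   n_skipped).
#' @export
run_grid <- function(panel, trait, ages = 1:19,
                     model_tag = c("AE", "ACE"),
                     design = c("five_group", "single_sex"),
                     min_pairs = 30,
                     ci_method = c("wald", "profile", "none"),
                     level = 0.95) {
  model_tag <- match.arg(model_tag)
  design <- match.arg(design)
  ci_method <- match.arg(ci_method)

  panel_ages <- sort(unique(panel$age[panel$trait == trait]))
  ages <- sort(unique(as.integer(ages)))
  ages <- intersect(ages, panel_ages)
  if (length(ages) == 0L)
    stop("requested ages do not intersect the panel's ages for trait '", trait, "'")
  if (length(ages) < 2L)
    stop("at least two ages are needed to form age pairs")

  sexes <- grid_sexes(design)
  rows <- list()
  n_conv <- 0L; n_skip <- 0L; n_cells <- 0L

  for (ji in seq_len(length(ages) - 1L)) {
    for (ki in seq((ji + 1L), length(ages))) {
      j <- ages[ji]; k <- ages[ki]
      n_cells <- n_cells + 1L
      pd <- pair_data(panel, trait, c(j, k))
      base <- do.call(rbind, lapply(sexes, function(s)
        cell_row(trait, model_tag, s, j, k)))
      base$n_pairs <- pd$n_families

      groups_ok <- if (design == "five_group")
        all(c("MZM", "MZF", "DZM", "DZF", "OSDZ") %in% unique(pd$group))
      else all(c("MZ", "DZ") %in% zyg_class(unique(pd$group)))

      if (pd$n_families < min_pairs || !groups_ok) {
        n_skip <- n_skip + 1L
        rows[[length(rows) + 1L]] <- base
        next
      }

      fit <- fit_model(pd, model_tag = model_tag, design = design)
      if (isTRUE(fit$converged)) n_conv <- n_conv + 1L

      for (si in seq_along(sexes)) {
        s <- sexes[si]
        sm <- fit$summary[fit$summary$sex == s, , drop = FALSE]
        base$skipped[si] <- FALSE
        base$converged[si] <- fit$converged
        base$r_trait[si] <- sm$rP
        base$r_A[si] <- sm$rA
        base$r_C[si] <- sm$rC
        base$r_E[si] <- sm$rE
        base$a1[si] <- sqrt(sm$A1); base$a2[si] <- sqrt(sm$A2)
        base$c1[si] <- sqrt(sm$C1); base$c2[si] <- sqrt(sm$C2)
        base$e1[si] <- sqrt(sm$E1); base$e2[si] <- sqrt(sm$E2)
        if (ci_method != "none") {
          sx <- if (design == "five_group") s else NULL
          ciA <- tryCatch(
            if (ci_method == "wald") wald_ci(fit, "rA", sx, level)
            else profile_ci(fit, "rA", sx, level),
            error = function(e) c(NA_real_, NA_real_))
          ciE <- tryCatch(
            if (ci_method == "wald") wald_ci(fit, "rE", sx, level)
            else profile_ci(fit, "rE", sx, level),
            error = function(e) c(NA_real_, NA_real_))
          base$r_A_lo[si] <- ciA[1]; base$r_A_hi[si] <- ciA[2]
          base$r_E_lo[si] <- ciE[1]; base$r_E_hi[si] <- ciE[2]
        }
      }
      rows[[length(rows) + 1L]] <- base
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grid_summary") <- list(n_cells = n_cells, n_converged = n_conv,
                                    n_skipped = n_skip)
  attr(out, "ages") <- ages
  attr(out, "design") <- design
  class(out) <- c("correlation_grid", "data.frame")
  out
}

#' Square-matrix serialization of a correlation grid
#'
#' Returns the grid's quantity as an ages x ages matrix in the standard
#' triangle convention: upper triangle = males, lower triangle = females,
#' diagonal NA. Single-sex grids fill both triangles symmetrically.
#'
#' @param grid a `correlation_grid`.
#' @param quantity grid column, e.g. `"r_A"`, `"r_trait"`, `"r_E"`.
#' @return numeric matrix with age dimnames.
#' @export
grid_matrix <- function(grid, quantity = "r_A") {
  stopifnot(inherits(grid, "correlation_grid"), quantity %in% names(grid))
  ages <- attr(grid, "ages")
  m <- matrix(NA_real_, length(ages), length(ages),
              dimnames = list(ages, ages))
  for (i in seq_len(nrow(grid))) {
    r <- grid[i, ]
    jj <- match(r$age_j, ages); kk <- match(r$age_k, ages)
    if (r$sex %in% c("M", "all")) m[jj, kk] <- r[[quantity]]  # upper: males
    if (r$sex %in% c("F", "all")) m[kk, jj] <- r[[quantity]]  # lower: females
  }
  m
}

#' @rdname grid_matrix
#' @param path CSV output path (`write_grid_csv`) or directory
#'   (`write_grid_matrices`).
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname grid_matrix
#' @param quantities quantities to serialize as square matrices.
#' @export
write_grid_matrices <- function(grid, path,
                                quantities = c("r_trait", "r_A", "r_E")) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (q in quantities) {
    utils::write.csv(grid_matrix(grid, q),
                     file.path(path, paste0(q, ".csv")))
  }
  invisible(path)
}

#' @export
print.correlation_grid <- function(x, ...) {
  s <- attr(x, "grid_summary")
  cat(sprintf("correlation_grid: %d cells (%d converged, %d skipped), ages %s\n",
              s$n_cells, s$n_converged, s$n_skipped,
              paste(range(attr(x, "ages")), collapse = "-")))
  NextMethod()
}
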