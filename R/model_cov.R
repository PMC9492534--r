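# Cholesky ACE/AE covariance structure for twin pairs.
#
# Per sex s the within-twin covariance of the v phenotypes (one trait at v
# ages) is Sigma(s) = L_A(s) L_A(s)' + L_C(s) L_C(s)' + L_E(s) L_E(s)' with
# lower-triangular path matrices.  The cross-twin block scales the additive
# part by 1 (MZ), 0.5 (SSDZ) or 0.5*rg_os (OSDZ), keeps the shared part at
# scale 1, and drops the unique part.  OSDZ pairs mix male (twin 1) and
# female (twin 2) path sets.

as_lower_tri <- function(L, label) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop(label, " must be square")
  if (nrow(L) > 1L && max(abs(L[upper.tri(L)])) > 0)
    stop(label, " must be lower triangular")
  L
}

# flip column signs so diagonal entries are >= 0 (leaves L L' unchanged)
fix_sign <- function(L) {
  for (j in seq_len(ncol(L))) if (L[j, j] < 0) L[, j] <- -L[, j]
  L
}

norm_sex_arg <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("M", "F") %in% names(x)))
    list(M = x$M, F = x$F)
  } else {
    list(M = x, F = x)
  }
}

#' Cholesky path coefficients of a twin ACE/AE model
#'
#' Bundles the lower-triangular path matrices for the additive-genetic (A),
#' shared-environment (C) and unique-environment (E) components, the
#' opposite-sex genetic scaling and zygosity-specific means into one object
#' consumed by [expected_pair_covariance()] and [pair_loglikelihood()].
#'
#' @param A,E lower-triangular v x v path matrices, either a single matrix
#'   (shared by both sexes) or `list(M = , F = )`.
#' @param C like `A`, or `NULL` for an AE model.
#' @param rg_os OSDZ additive-genetic scaling in `[0, 1]` (cross-twin
#'   genetic correlation is `0.5 * rg_os`).
#' @param means v x 2 matrix of means (columns `MZ`, `DZ`) or
#'   `list(M = , F = )` of such; defaults to zero (residualized scale).
#' @return object of class `cholesky_paths`.
#' @examples
#' p <- cholesky_paths(A = sqrt(0.6), E = sqrt(0.4))
#' expected_pair_covariance(p, "MZM")
#' @export
cholesky_paths <- function(A, E, C = NULL, rg_os = 1, means = NULL) {
  A <- lapply(norm_sex_arg(A), as_lower_tri, label = "A")
  E <- lapply(norm_sex_arg(E), as_lower_tri, label = "E")
  v <- nrow(A$M)
  if (nrow(E$M) != v) stop("A and E must have the same dimension")
  if (!is.null(C)) {
    C <- lapply(norm_sex_arg(C), as_lower_tri, label = "C")
    if (nrow(C$M) != v) stop("A and C must have the same dimension")
  }
  if (rg_os < 0 || rg_os > 1) stop("rg_os must lie in [0, 1]")
  if (is.null(means)) means <- matrix(0, v, 2, dimnames = list(NULL, c("MZ", "DZ")))
  means <- norm_sex_arg(means)
  for (s in c("M", "F")) {
    means[[s]] <- as.matrix(means[[s]])
    if (!all(dim(means[[s]]) == c(v, 2)))
      stop("means must be a v x 2 matrix (columns MZ, DZ)")
    colnames(means[[s]]) <- c("MZ", "DZ")
  }
  structure(list(A = A, C = C, E = E, rg_os = rg_os, means = means, n_var = v),
            class = "cholesky_paths")
}

zyg_class <- function(group) ifelse(substr(group, 1, 2) == "MZ", "MZ", "DZ")

#' Model-implied covariance matrix of a twin pair
#'
#' Expected covariance of the stacked vector
#' (twin1 at age j, twin1 at age k, twin2 at age j, twin2 at age k)
#' (length 2 in the univariate case) under the Cholesky structure, for one
#' zygosity group. The result is symmetric positive semidefinite by
#' construction.
#'
#' @param paths a [cholesky_paths()] object.
#' @param zygosity_group one of `"MZM"`, `"MZF"`, `"DZM"`, `"DZF"`,
#'   `"OSDZ"`.
#' @return 2v x 2v covariance matrix.
#' @export
expected_pair_covariance <- function(paths, zygosity_group) {
  stopifnot(inherits(paths, "cholesky_paths"))
  sexes <- group_sexes(zygosity_group)
  kA <- group_kA(zygosity_group, paths$rg_os)
  LA1 <- paths$A[[sexes[1]]]; LA2 <- paths$A[[sexes[2]]]
  LE1 <- paths$E[[sexes[1]]]; LE2 <- paths$E[[sexes[2]]]
  zeroC <- is.null(paths$C)
  LC1 <- if (zeroC) NULL else paths$C[[sexes[1]]]
  LC2 <- if (zeroC) NULL else paths$C[[sexes[2]]]

  S11 <- tcrossprod(LA1) + tcrossprod(LE1) + if (zeroC) 0 else tcrossprod(LC1)
  S22 <- tcrossprod(LA2) + tcrossprod(LE2) + if (zeroC) 0 else tcrossprod(LC2)
  S12 <- kA * tcrossprod(LA1, LA2) + if (zeroC) 0 else tcrossprod(LC1, LC2)
  rbind(cbind(S11, S12), cbind(t(S12), S22))
}

pair_mean_vector <- function(paths, zygosity_group) {
  sexes <- group_sexes(zygosity_group)
  z <- zyg_class(zygosity_group)
  c(paths$means[[sexes[1]]][, z], paths$means[[sexes[2]]][, z])
}
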