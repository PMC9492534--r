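# Full-information ML likelihood for twin-pair vectors with missing
# elements.  Families are grouped by (zygosity group, missingness pattern)
# and summarized by sufficient statistics (n, sum x, sum x x'), so one
# likelihood evaluation costs O(#patterns) small matrix operations
# regardless of sample size.

#' Assemble paired twin data for one trait and one or two ages
#'
#' Builds, per family, the stacked vector
#' (twin1 at age j, twin1 at age k, twin2 at age j, twin2 at age k)
#' (length 2 for a single age) of residualized values, with NA marking
#' missing elements. Twins are ordered by `twin_index`, except OSDZ pairs
#' where the male twin is always first (the model's cross-sex convention).
#' Families in which one co-twin is entirely unobserved are dropped and
#' counted: after residualization they carry no co-twin covariance
#' information. Families are sorted by (group, family id) so the result is
#' invariant to input row order.
#'
#' @param panel a `phenotype_panel` from [build_panel()].
#' @param trait one of the panel's traits (e.g. `"logBMI"`, `"height"`).
#' @param ages one or two integer ages.
#' @return list of class `paired_age_data`: `y` (n x 2v matrix), `group`
#'   (zygosity group per family), `family_id`, `ages`, `trait`, `n_var`,
#'   `n_families`, `n_dropped`.
#' @export
pair_data <- function(panel, trait, ages) {
  stopifnot(length(ages) %in% 1:2)
  ages <- sort(as.integer(ages))
  v <- length(ages)
  d <- panel[panel$trait == trait & panel$age %in% ages, , drop = FALSE]
  if (nrow(d) == 0L) stop("no panel rows for trait '", trait, "' at the requested ages")

  fams <- sort(unique(d$family_id))
  fam_i <- match(d$family_id, fams)
  n <- length(fams)
  group <- character(n)
  group[fam_i] <- d$zygosity_group

  # twin slot: 1/2 by twin_index; OSDZ male first
  slot <- d$twin_index
  os <- d$zygosity_group == "OSDZ"
  slot[os] <- ifelse(d$sex[os] == "M", 1L, 2L)

  y <- matrix(NA_real_, n, 2L * v)
  col <- (slot - 1L) * v + match(d$age, ages)
  y[cbind(fam_i, col)] <- d$value

  t1_missing <- rowSums(!is.na(y[, seq_len(v), drop = FALSE])) == 0L
  t2_missing <- rowSums(!is.na(y[, v + seq_len(v), drop = FALSE])) == 0L
  drop <- t1_missing | t2_missing
  keep <- which(!drop)
  ord <- keep[order(group[keep], fams[keep])]

  structure(list(y = y[ord, , drop = FALSE],
                 group = group[ord],
                 family_id = fams[ord],
                 ages = ages, trait = trait, n_var = v,
                 n_families = length(ord), n_dropped = sum(drop)),
            class = "paired_age_data")
}

# sufficient statistics per (group, missingness pattern)
pair_suff_stats <- function(pd) {
  y <- pd$y
  pat <- apply(!is.na(y), 1L, function(z) paste(as.integer(z), collapse = ""))
  key <- paste(pd$group, pat, sep = ":")
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    idx <- which(!is.na(y[rows[1], ]))
    yy <- y[rows, idx, drop = FALSE]
    out[[k]] <- list(group = pd$group[rows[1]],
                     idx = idx,
                     n = length(rows),
                     sx = colSums(yy),
                     sxx = crossprod(yy))
  }
  out
}

# core evaluator: sum of MVN log-densities over pattern groups.
# group_cov / group_mu: named lists over zygosity groups present.
# Fast path assumes every observed submatrix is positive definite; a chol
# failure reroutes through the jittered per-pattern path.
loglik_from_stats <- function(stats, group_cov, group_mu, jitter = 1e-8) {
  res <- tryCatch({
    ll <- 0
    for (st in stats) {
      S <- group_cov[[st$group]][st$idx, st$idx, drop = FALSE]
      mu <- group_mu[[st$group]][st$idx]
      k <- length(st$idx)
      ch <- chol(S)
      logdet <- 2 * sum(log(diag(ch)))
      Sinv <- chol2inv(ch)
      M <- st$sxx - tcrossprod(st$sx, mu) - tcrossprod(mu, st$sx) +
        st$n * tcrossprod(mu)
      ll <- ll - 0.5 * (st$n * (k * log(2 * pi) + logdet) + sum(Sinv * M))
    }
    list(ll = ll, n_jittered = 0L)
  }, error = function(e) NULL)
  if (is.null(res))
    res <- loglik_from_stats_safe(stats, group_cov, group_mu, jitter)
  res
}

loglik_from_stats_safe <- function(stats, group_cov, group_mu, jitter = 1e-8) {
  ll <- 0
  n_jit <- 0L
  for (st in stats) {
    S <- group_cov[[st$group]][st$idx, st$idx, drop = FALSE]
    mu <- group_mu[[st$group]][st$idx]
    k <- length(st$idx)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      n_jit <- n_jit + st$n
      ch <- tryCatch(chol(S + diag(jitter, k)), error = function(e) NULL)
      if (is.null(ch)) return(list(ll = -Inf, n_jittered = n_jit))
    }
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    M <- st$sxx - tcrossprod(st$sx, mu) - tcrossprod(mu, st$sx) +
      st$n * tcrossprod(mu)
    ll <- ll - 0.5 * (st$n * (k * log(2 * pi) + logdet) + sum(Sinv * M))
  }
  list(ll = ll, n_jittered = n_jit)
}

#' Log-likelihood of paired twin data under a Cholesky model
#'
#' Sum over families of the multivariate-normal log-density of each
#' family's observed sub-vector, with mean and covariance sub-setted from
#' the zygosity-appropriate expected pair mean/covariance
#' (full-information handling of missing elements). A family whose observed
#' covariance sub-matrix is numerically singular contributes through a
#' 1e-8 diagonal jitter and is counted in the `"n_jittered"` attribute.
#'
#' @param data a `paired_age_data` from [pair_data()].
#' @param paths a [cholesky_paths()] object of matching dimension.
#' @return scalar log-likelihood with attribute `n_jittered`.
#' @export
pair_loglikelihood <- function(data, paths) {
  stopifnot(inherits(data, "paired_age_data"), inherits(paths, "cholesky_paths"))
  if (paths$n_var != data$n_var)
    stop("paths dimension does not match the data (", data$n_var, " variables)")
  groups <- unique(data$group)
  group_cov <- lapply(groups, function(g) expected_pair_covariance(paths, g))
  group_mu <- lapply(groups, function(g) pair_mean_vector(paths, g))
  names(group_cov) <- names(group_mu) <- groups
  res <- loglik_from_stats(pair_suff_stats(data), group_cov, group_mu)
  structure(res$ll, n_jittered = res$n_jittered)
}
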