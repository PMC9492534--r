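# Maximum-likelihood fitting of univariate / bivariate Cholesky ACE and AE
# models.  Path entries and means are estimated as free reals (diagonal
# signs fixed after the fact; L L' is invariant), rg_os through a logistic
# map onto [0, 1].  Optimization is quasi-Newton (BFGS) with central-
# difference gradients, started from method-of-moments estimates.

n_lower_tri <- function(v) v * (v + 1L) / 2L

mk_lower <- function(vals, v) {
  L <- matrix(0, v, v)
  L[lower.tri(L, diag = TRUE)] <- vals
  L
}

lower_vals <- function(L) L[lower.tri(L, diag = TRUE)]

make_mspec <- function(n_var, model_tag, design) {
  comps <- if (model_tag == "ACE") c("A", "C", "E") else c("A", "E")
  sexkeys <- if (design == "five_group") c("M", "F") else "S"
  npL <- n_lower_tri(n_var)
  pos <- list(L = list(), mu = list())
  p <- 0L
  for (s in sexkeys) {
    pos$L[[s]] <- list()
    for (comp in comps) {
      pos$L[[s]][[comp]] <- p + seq_len(npL)
      p <- p + npL
    }
  }
  pos$rg <- NA_integer_
  if (design == "five_group") {
    pos$rg <- p + 1L
    p <- p + 1L
  }
  for (s in sexkeys) {
    pos$mu[[s]] <- list()
    for (z in c("MZ", "DZ")) {
      pos$mu[[s]][[z]] <- p + seq_len(n_var)
      p <- p + n_var
    }
  }
  list(n_var = n_var, model_tag = model_tag, design = design,
       comps = comps, sexkeys = sexkeys, n_par = p, pos = pos)
}

sexkey_of <- function(ms, sex) if (ms$design == "five_group") sex else "S"

# per-group structural info for the likelihood
group_structs <- function(ms, groups) {
  lapply(stats::setNames(groups, groups), function(g) {
    sx <- group_sexes(g)
    list(s1 = sexkey_of(ms, sx[1]), s2 = sexkey_of(ms, sx[2]),
         zyg = zyg_class(g), os = g == "OSDZ",
         k0 = if (zyg_class(g) == "MZ") 1 else 0.5)
  })
}

theta_decode <- function(theta, ms) {
  L <- list(); XX <- list(); mu <- list()
  for (s in ms$sexkeys) {
    L[[s]] <- list(); XX[[s]] <- list()
    for (comp in ms$comps) {
      Lm <- mk_lower(theta[ms$pos$L[[s]][[comp]]], ms$n_var)
      L[[s]][[comp]] <- Lm
      XX[[s]][[comp]] <- tcrossprod(Lm)
    }
    mu[[s]] <- list(MZ = theta[ms$pos$mu[[s]]$MZ], DZ = theta[ms$pos$mu[[s]]$DZ])
  }
  rg <- if (ms$design == "five_group") stats::plogis(theta[ms$pos$rg]) else 1
  list(L = L, XX = XX, mu = mu, rg = rg)
}

group_cov_mu <- function(dec, gs, ms) {
  withC <- "C" %in% ms$comps
  cov <- list(); mu <- list()
  for (g in names(gs)) {
    st <- gs[[g]]
    X1 <- dec$XX[[st$s1]]; X2 <- dec$XX[[st$s2]]
    S11 <- X1$A + X1$E + if (withC) X1$C else 0
    S22 <- X2$A + X2$E + if (withC) X2$C else 0
    kA <- if (st$os) 0.5 * dec$rg else st$k0
    LA1 <- dec$L[[st$s1]]$A; LA2 <- dec$L[[st$s2]]$A
    S12 <- kA * tcrossprod(LA1, LA2)
    if (withC) S12 <- S12 + tcrossprod(dec$L[[st$s1]]$C, dec$L[[st$s2]]$C)
    cov[[g]] <- rbind(cbind(S11, S12), cbind(t(S12), S22))
    mu[[g]] <- c(dec$mu[[st$s1]][[st$zyg]], dec$mu[[st$s2]][[st$zyg]])
  }
  list(cov = cov, mu = mu)
}

num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xm <- x
    xp[i] <- x[i] + hi
    xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

# ---- objective with analytic score ---------------------------------------
# Score equations of the FIML objective: per (group, pattern) block with
# observed index set o, mean mu_o, covariance S_o and moment matrix
# M = sxx - sx mu' - mu sx' + n mu mu',
#   d ll / d S  = -(n S^-1 - S^-1 M S^-1) / 2     (symmetric),
#   d ll / d mu = S^-1 (sx - n mu),
# chained through S = L L' blocks:  d tr(G L L') / dL = 2 G L, and for the
# cross-twin block with distinct path sets, d/dL1 = 2 kappa G12 L2.

make_objective <- function(stats_list, gs, ms) {
  full_dim <- 2L * ms$n_var
  i1 <- seq_len(ms$n_var)
  i2 <- ms$n_var + i1
  withC <- "C" %in% ms$comps
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  cache$n_jittered <- 0L

  fn <- function(theta) {
    dec <- theta_decode(theta, ms)
    gm <- group_cov_mu(dec, gs, ms)
    res <- loglik_from_stats(stats_list, gm$cov, gm$mu)
    cache$n_jittered <- res$n_jittered
    if (!is.finite(res$ll)) return(1e10)
    -res$ll
  }

  gr <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$grad)
    dec <- theta_decode(theta, ms)
    gm <- group_cov_mu(dec, gs, ms)

    GS <- lapply(gm$cov, function(S) matrix(0, full_dim, full_dim))
    gmu <- lapply(gm$cov, function(S) numeric(full_dim))
    ok <- TRUE
    for (st in stats_list) {
      S <- gm$cov[[st$group]][st$idx, st$idx, drop = FALSE]
      mu <- gm$mu[[st$group]][st$idx]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch))
        ch <- tryCatch(chol(S + diag(1e-8, length(st$idx))),
                       error = function(e) NULL)
      if (is.null(ch)) { ok <- FALSE; break }
      Sinv <- chol2inv(ch)
      M <- st$sxx - tcrossprod(st$sx, mu) - tcrossprod(mu, st$sx) +
        st$n * tcrossprod(mu)
      GS[[st$group]][st$idx, st$idx] <- GS[[st$group]][st$idx, st$idx] -
        0.5 * (st$n * Sinv - Sinv %*% M %*% Sinv)
      gmu[[st$group]][st$idx] <- gmu[[st$group]][st$idx] +
        drop(Sinv %*% (st$sx - st$n * mu))
    }
    if (!ok) {  # fall back to finite differences near a degenerate point
      g <- num_grad(fn, theta)
      cache$theta <- theta
      cache$grad <- g
      return(g)
    }

    g <- numeric(ms$n_par)
    ltri <- lower.tri(matrix(0, ms$n_var, ms$n_var), diag = TRUE)
    for (gname in names(gs)) {
      st <- gs[[gname]]
      G <- GS[[gname]]
      G11 <- G[i1, i1, drop = FALSE]
      G22 <- G[i2, i2, drop = FALSE]
      G12 <- G[i1, i2, drop = FALSE]
      kA <- if (st$os) 0.5 * dec$rg else st$k0
      comps <- if (withC) c(A = kA, C = 1, E = 0) else c(A = kA, E = 0)
      if (st$s1 == st$s2) {
        s <- st$s1
        W <- 2 * (G11 + G22)
        X <- 2 * (G12 + t(G12))
        for (comp in names(comps)) {
          L <- dec$L[[s]][[comp]]
          gm_c <- (W + comps[[comp]] * X) %*% L
          pos <- ms$pos$L[[s]][[comp]]
          g[pos] <- g[pos] + gm_c[ltri]
        }
      } else {
        for (comp in names(comps)) {
          L1 <- dec$L[[st$s1]][[comp]]
          L2 <- dec$L[[st$s2]][[comp]]
          kap <- comps[[comp]]
          g1 <- 2 * G11 %*% L1 + 2 * kap * G12 %*% L2
          g2 <- 2 * G22 %*% L2 + 2 * kap * t(G12) %*% L1
          p1 <- ms$pos$L[[st$s1]][[comp]]
          p2 <- ms$pos$L[[st$s2]][[comp]]
          g[p1] <- g[p1] + g1[ltri]
          g[p2] <- g[p2] + g2[ltri]
        }
      }
      if (st$os && ms$design == "five_group") {
        LA12 <- tcrossprod(dec$L[[st$s1]]$A, dec$L[[st$s2]]$A)
        g[ms$pos$rg] <- g[ms$pos$rg] +
          2 * sum(G12 * LA12) * 0.5 * dec$rg * (1 - dec$rg)
      }
      pm1 <- ms$pos$mu[[st$s1]][[st$zyg]]
      pm2 <- ms$pos$mu[[st$s2]][[st$zyg]]
      g[pm1] <- g[pm1] + gmu[[gname]][i1]
      g[pm2] <- g[pm2] + gmu[[gname]][i2]
    }
    g <- -g   # gradient of the negative log-likelihood
    cache$theta <- theta
    cache$grad <- g
    g
  }

  list(fn = fn, gr = gr, cache = cache)
}

# ---- method-of-moments starting values -----------------------------------

moment_start <- function(data, ms) {
  y <- data$y
  v <- ms$n_var
  zyg <- zyg_class(data$group)
  sd_i <- vapply(seq_len(v), function(i)
    stats::sd(c(y[, i], y[, v + i]), na.rm = TRUE), 0)
  sd_i[!is.finite(sd_i) | sd_i <= 0] <- 1

  r_by_class <- function(z, i) {
    rows <- zyg == z
    r <- double_entry_cor(y[rows, i], y[rows, v + i])
    if (!is.finite(r)) r <- if (z == "MZ") 0.5 else 0.3
    min(max(r, -0.95), 0.99)
  }

  sh <- matrix(0, v, 3)  # a2, c2, e2 per variable
  for (i in seq_len(v)) {
    fe <- falconer_estimates(r_by_class("MZ", i), r_by_class("DZ", i))
    s <- pmax(c(fe$a2, fe$c2, fe$e2), 0.05)
    sh[i, ] <- s / sum(s)
  }

  SA <- diag(sh[, 1], v); SC <- diag(sh[, 2], v); SE <- diag(sh[, 3], v)
  if (v == 2L) {
    ys <- y
    ys[, c(1, 3)] <- ys[, c(1, 3)] / sd_i[1]
    ys[, c(2, 4)] <- ys[, c(2, 4)] / sd_i[2]
    ct <- function(z) {
      rows <- zyg == z
      r <- double_entry_cov(ys[rows, 1], ys[rows, 4], ys[rows, 3], ys[rows, 2])
      if (!is.finite(r)) r <- 0
      r
    }
    wp <- stats::cov(c(ys[, 1], ys[, 3]), c(ys[, 2], ys[, 4]),
                     use = "pairwise.complete.obs")
    if (!is.finite(wp)) wp <- 0
    mb <- moment_bivariate(ct("MZ"), ct("DZ"), wp)
    cap <- function(x, m) sign(x) * min(abs(x), m)
    SA[1, 2] <- SA[2, 1] <- cap(mb$covA, 0.95 * sqrt(SA[1, 1] * SA[2, 2]))
    SC[1, 2] <- SC[2, 1] <- cap(mb$covC, 0.95 * sqrt(SC[1, 1] * SC[2, 2]))
    SE[1, 2] <- SE[2, 1] <- cap(mb$covE, 0.95 * sqrt(SE[1, 1] * SE[2, 2]))
  }
  if (ms$model_tag == "AE") {  # fold C into A for the AE start
    SA <- SA + SC
  }

  D <- diag(sd_i, v)
  safe_chol <- function(S) {
    S <- D %*% S %*% D
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    S <- es$vectors %*% (pmax(es$values, 1e-4) * t(es$vectors))
    t(chol(S))
  }

  theta <- numeric(ms$n_par)
  for (s in ms$sexkeys) {
    theta[ms$pos$L[[s]]$A] <- lower_vals(safe_chol(SA))
    if ("C" %in% ms$comps) theta[ms$pos$L[[s]]$C] <- lower_vals(safe_chol(SC))
    theta[ms$pos$L[[s]]$E] <- lower_vals(safe_chol(SE))
  }
  if (ms$design == "five_group") theta[ms$pos$rg] <- stats::qlogis(0.9)
  for (s in ms$sexkeys) {
    for (z in c("MZ", "DZ")) {
      rows <- zyg == z
      mz <- vapply(seq_len(v), function(i)
        mean(c(y[rows, i], y[rows, v + i]), na.rm = TRUE), 0)
      mz[!is.finite(mz)] <- 0
      theta[ms$pos$mu[[s]][[z]]] <- mz
    }
  }
  theta
}

# ---- derived quantities ---------------------------------------------------

derived_components <- function(dec, ms) {
  withC <- "C" %in% ms$comps
  out <- list()
  for (s in ms$sexkeys) {
    VA <- dec$XX[[s]]$A
    VC <- if (withC) dec$XX[[s]]$C else matrix(0, ms$n_var, ms$n_var)
    VE <- dec$XX[[s]]$E
    V <- VA + VC + VE
    out[[s]] <- list(VA = VA, VC = VC, VE = VE, V = V)
  }
  out
}

quantity_value <- function(theta, ms, quantity, sex = NULL) {
  dec <- theta_decode(theta, ms)
  s <- if (is.null(sex)) ms$sexkeys[1] else sexkey_of(ms, sex)
  cmp <- derived_components(dec, ms)[[s]]
  corr_of <- function(Vx) {
    if (Vx[1, 1] <= 0 || Vx[2, 2] <= 0) return(NA_real_)
    Vx[1, 2] / sqrt(Vx[1, 1] * Vx[2, 2])
  }
  switch(quantity,
         rA = corr_of(cmp$VA),
         rC = corr_of(cmp$VC),
         rE = corr_of(cmp$VE),
         rP = corr_of(cmp$V),
         a2 = cmp$VA[1, 1] / cmp$V[1, 1],
         c2 = cmp$VC[1, 1] / cmp$V[1, 1],
         e2 = cmp$VE[1, 1] / cmp$V[1, 1],
         rg_os = dec$rg,
         stop("unknown quantity: ", quantity))
}

fit_summary_table <- function(theta, ms) {
  dec <- theta_decode(theta, ms)
  cmp <- derived_components(dec, ms)
  rows <- lapply(ms$sexkeys, function(s) {
    k <- cmp[[s]]
    v <- ms$n_var
    shares <- function(Vx) diag(as.matrix(Vx)) / diag(as.matrix(k$V))
    r_of <- function(Vx) if (v == 2L)
      standardize_correlation(Vx[1, 2], Vx[1, 1], Vx[2, 2]) else NA_real_
    rC <- if (v == 2L && max(abs(k$VC)) > 0) r_of(k$VC) else NA_real_
    row <- data.frame(sex = if (s == "S") "all" else s)
    A <- shares(k$VA); C <- shares(k$VC); E <- shares(k$VE)
    for (i in seq_len(v)) {
      row[[paste0("A", i)]] <- A[i]
      row[[paste0("C", i)]] <- C[i]
      row[[paste0("E", i)]] <- E[i]
    }
    if (v == 2L) {
      row$rA <- r_of(k$VA)
      row$rC <- rC
      row$rE <- r_of(k$VE)
      row$rP <- r_of(k$V)
    }
    for (i in seq_len(v)) {
      row[[paste0("total_var", i)]] <- k$V[i, i]
    }
    row
  })
  do.call(rbind, rows)
}

# ---- fitting --------------------------------------------------------------

#' Fit a twin ACE or AE model by maximum likelihood
#'
#' Full-information ML estimation of a univariate or bivariate Cholesky
#' model on paired twin data. `design = "single_sex"` estimates one path
#' set (OSDZ pairs, if present, enter with genetic scaling 0.5);
#' `design = "five_group"` estimates male and female path sets plus the
#' free OSDZ genetic scaling `rg_os` (sex-limitation model) and requires
#' all five zygosity groups. Zygosity-specific mean parameters are always
#' estimated. Fits are deterministic: starting values come from the
#' method-of-moments oracle and restarts use fixed perturbations.
#'
#' @param data a `paired_age_data` from [pair_data()].
#' @param model_tag `"AE"` (main model) or `"ACE"`.
#' @param design `"single_sex"` or `"five_group"`.
#' @param start optional starting parameter vector (expert use).
#' @param max_restarts perturbed-restart attempts after a failed
#'   convergence check.
#' @return object of class `twin_fit`: estimates (`summary`, `rg_os`,
#'   `paths`), `logL`, convergence diagnostics, group counts.
#' @export
fit_model <- function(data, model_tag = c("AE", "ACE"),
                      design = c("single_sex", "five_group"),
                      start = NULL, max_restarts = 3L) {
  model_tag <- match.arg(model_tag)
  design <- match.arg(design)
  stopifnot(inherits(data, "paired_age_data"))

  groups <- unique(data$group)
  zc <- unique(zyg_class(groups))
  if (!all(c("MZ", "DZ") %in% zc))
    stop("both MZ and DZ pairs are required for identification")
  if (design == "five_group" &&
      !all(c("MZM", "MZF", "DZM", "DZF", "OSDZ") %in% groups))
    stop("five_group design requires all five zygosity groups")

  ms <- make_mspec(data$n_var, model_tag, design)
  if (data$n_families < ms$n_par)
    stop(sprintf("only %d pairs for %d free parameters", data$n_families, ms$n_par))

  stats_list <- pair_suff_stats(data)
  gs <- group_structs(ms, groups)
  obj <- make_objective(stats_list, gs, ms)

  theta0 <- if (is.null(start)) moment_start(data, ms) else start
  gtol <- 1e-5

  run_once <- function(th0) {
    opt <- stats::optim(th0, obj$fn, gr = obj$gr, method = "BFGS",
                        control = list(maxit = 600, reltol = 1e-12))
    gn <- max(abs(obj$gr(opt$par))) / data$n_families
    list(par = opt$par, value = opt$value, counts = opt$counts,
         ok = opt$convergence == 0 && gn < gtol, grad_norm = gn)
  }

  best <- run_once(theta0)
  attempt <- 0L
  perturb <- c(0.9, 1.1, 0.75)
  while (!best$ok && attempt < max_restarts) {
    attempt <- attempt + 1L
    th <- theta0
    pathpos <- unlist(lapply(ms$sexkeys, function(s) unlist(ms$pos$L[[s]])))
    th[pathpos] <- th[pathpos] * perturb[attempt]
    cand <- run_once(th)
    if (cand$value < best$value || (cand$ok && !best$ok)) best <- cand
  }

  # evaluate once more at the optimum to refresh the jitter count
  obj$fn(best$par)
  n_jittered <- obj$cache$n_jittered
  jitter_ok <- n_jittered <= 0.01 * data$n_families

  # sign-fixed path matrices for reporting
  dec <- theta_decode(best$par, ms)
  paths <- list()
  for (s in ms$sexkeys) paths[[s]] <- lapply(dec$L[[s]], fix_sign)

  fit <- structure(list(
    theta = best$par,
    mspec = ms,
    logL = -best$value,
    converged = best$ok && jitter_ok,
    grad_norm = best$grad_norm,
    n_iter = unname(best$counts[1]),
    n_restarts = attempt,
    n_jittered = n_jittered,
    model_tag = model_tag,
    design = design,
    trait = data$trait,
    ages = data$ages,
    n_var = data$n_var,
    n_pairs = table(data$group),
    n_families = data$n_families,
    n_dropped = data$n_dropped,
    rg_os = dec$rg,
    paths = paths,
    means = dec$mu,
    summary = fit_summary_table(best$par, ms),
    stats = stats_list,
    groups = groups,
    obj = NULL), class = "twin_fit")
  fit$obj <- obj
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("twin_fit: %s model, %s design, trait %s, ages %s\n",
              x$model_tag, x$design, x$trait, paste(x$ages, collapse = "/")))
  cat(sprintf("  logL = %.4f  converged = %s  (grad %.2e, %d pairs, %d dropped)\n",
              x$logL, x$converged, x$grad_norm, x$n_families, x$n_dropped))
  if (x$design == "five_group") cat(sprintf("  rg_os = %.3f\n", x$rg_os))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

# rebuild the objective of a fit (used when the closure was stripped,
# e.g. after deserialization)
fit_objective <- function(fit) {
  if (is.list(fit$obj) && is.function(fit$obj$fn)) return(fit$obj)
  make_objective(fit$stats, group_structs(fit$mspec, fit$groups), fit$mspec)
}

#' Wald (delta-method) confidence interval for a fitted quantity
#'
#' Numerical-Hessian observed-information interval for a derived quantity
#' of a [fit_model()] fit; correlation quantities are clipped to
#' `[-1, 1]`.
#'
#' @param fit a `twin_fit`.
#' @param quantity one of `"rA"`, `"rC"`, `"rE"`, `"rP"` (bivariate),
#'   `"a2"`, `"c2"`, `"e2"` (univariate), `"rg_os"`.
#' @param sex `"M"` or `"F"` for five-group fits; ignored otherwise.
#' @param level confidence level.
#' @return numeric `c(lower, upper)` with attributes `estimate` and `se`.
#' @export
wald_ci <- function(fit, quantity, sex = NULL, level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  obj <- fit_objective(fit)
  p <- length(fit$theta)
  # the observed information at the MLE is reused across quantities
  if (is.null(obj$cache$Vtheta)) {
    H <- stats::optimHess(fit$theta, obj$fn, obj$gr,
                          control = list(ndeps = rep(1e-5, p)))
    obj$cache$Vtheta <- tryCatch(solve(H), error = function(e) pseudo_inverse(H))
  }
  Vtheta <- obj$cache$Vtheta
  qf <- function(th) quantity_value(th, fit$mspec, quantity, sex)
  est <- qf(fit$theta)
  g <- num_grad(qf, fit$theta, h = 1e-5)
  se <- sqrt(max(0, drop(t(g) %*% Vtheta %*% g)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(est - zq * se, est + zq * se)
  if (quantity %in% c("rA", "rC", "rE", "rP"))
    ci <- pmin(pmax(ci, -1), 1)
  structure(ci, estimate = est, se = se, method = "wald")
}

# Moore-Penrose pseudo-inverse fallback for a singular information matrix
pseudo_inverse <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}
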