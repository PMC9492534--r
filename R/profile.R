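# Profile-likelihood confidence intervals.  The generic machinery brackets
# and bisects the points where the profiled log-likelihood drops
# chi^2_1(level)/2 below the maximum; fit-specific code supplies the
# profile function by refitting all nuisance parameters under an equality
# constraint imposed through reparameterization.

#' Profile-likelihood interval from a profile function
#'
#' Finds, on each side of the maximum, the quantity value where
#' `2 * (logL_max - profile(q)) = qchisq(level, 1)` by outward stepping
#' followed by monotone bisection. An end that cannot be bracketed inside
#' `[lower, upper]` is returned at the bound and flagged one-sided.
#'
#' @param prof_fn function of the scalar quantity returning the profiled
#'   log-likelihood (maximized over all other parameters).
#' @param mle value of the quantity at the full maximum.
#' @param logL_max maximized log-likelihood.
#' @param level confidence level (default 0.95).
#' @param lower,upper hard bounds for the quantity (e.g. -1, 1 for a
#'   correlation).
#' @param step initial outward step of the bracketing phase.
#' @param tol bisection tolerance on the quantity scale.
#' @return `c(lower, upper)` with attribute `one_sided` (logical length 2).
#' @examples
#' # N(mu, 1) likelihood from a sample: profile CI matches the closed form
#' x <- rnorm(50)
#' prof <- function(mu) sum(dnorm(x, mu, 1, log = TRUE))
#' profile_interval(prof, mean(x), prof(mean(x)), lower = -10, upper = 10)
#' @export
profile_interval <- function(prof_fn, mle, logL_max, level = 0.95,
                             lower = -Inf, upper = Inf,
                             step = 0.02, tol = 1e-3) {
  thresh <- stats::qchisq(level, 1) / 2
  # g < 0 inside the interval, g > 0 outside
  g <- function(q) (logL_max - prof_fn(q)) - thresh

  one_side <- function(dir) {
    bound <- if (dir > 0) upper else lower
    q_in <- mle
    s <- step
    repeat {
      q_out <- q_in + dir * s
      hit_bound <- (dir > 0 && q_out >= bound) || (dir < 0 && q_out <= bound)
      if (hit_bound) q_out <- bound
      val <- g(q_out)
      if (is.finite(val) && val > 0) break
      if (hit_bound) return(list(q = bound, one_sided = TRUE))
      q_in <- q_out
      s <- 2 * s
    }
    lo <- min(q_in, q_out); hi <- max(q_in, q_out)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) {
        if (dir > 0) hi <- mid else lo <- mid
      } else {
        if (dir > 0) lo <- mid else hi <- mid
      }
    }
    list(q = (lo + hi) / 2, one_sided = FALSE)
  }

  left <- one_side(-1)
  right <- one_side(1)
  structure(c(left$q, right$q),
            one_sided = c(left$one_sided, right$one_sided),
            level = level)
}

# ---- constraint injectors -------------------------------------------------
# Each injector maps (reduced theta, q0) -> full theta with the quantity
# pinned at q0, together with the reduced starting point taken from the MLE.

make_injector <- function(fit, quantity, sex) {
  ms <- fit$mspec
  s <- if (is.null(sex)) ms$sexkeys[1] else sexkey_of(ms, sex)

  if (quantity %in% c("rA", "rC", "rE")) {
    if (ms$n_var != 2L)
      stop("component correlations are defined for bivariate fits only")
    comp <- substr(quantity, 2, 2)
    if (!comp %in% ms$comps)
      stop("quantity ", quantity, " is not in an ", ms$model_tag, " model")
    # positions of (l21, l22) of the relevant L for this sex; lower-tri
    # order is (1,1), (2,1), (2,2)
    posL <- ms$pos$L[[s]][[comp]]
    fixed <- posL[2:3]
    free <- setdiff(seq_len(ms$n_par), fixed)
    inject <- function(th_red, q0) {
      t_len <- th_red[length(th_red)]
      th <- numeric(ms$n_par)
      th[free] <- th_red[-length(th_red)]
      th[fixed] <- abs(t_len) * c(q0, sqrt(max(0, 1 - q0^2)))
      th
    }
    reduce <- function(theta) {
      c(theta[free], sqrt(sum(theta[fixed]^2)))
    }
    grad_map <- function(grad_full, th_red, q0) {
      t_len <- th_red[length(th_red)]
      dt <- sign(t_len + (t_len == 0)) * c(q0, sqrt(max(0, 1 - q0^2)))
      c(grad_full[free], sum(grad_full[fixed] * dt))
    }
    return(list(inject = inject, reduce = reduce, grad_map = grad_map,
                lower = -1, upper = 1))
  }

  if (quantity %in% c("a2", "c2", "e2")) {
    if (ms$n_var != 1L)
      stop("variance shares are profiled on univariate fits")
    comp <- toupper(substr(quantity, 1, 1))
    if (!comp %in% ms$comps)
      stop("quantity ", quantity, " is not in an ", ms$model_tag, " model")
    others <- setdiff(ms$comps, comp)
    posc <- ms$pos$L[[s]][[comp]]
    poso <- lapply(others, function(o) ms$pos$L[[s]][[o]])
    fixed <- c(posc, unlist(poso))
    free <- setdiff(seq_len(ms$n_par), fixed)
    n_extra <- if (length(others) == 2L) 2L else 1L
    inject <- function(th_red, q0) {
      extra <- th_red[seq(length(th_red) - n_extra + 1L, length(th_red))]
      t_sd <- extra[1]                       # overall scale (sd of total)
      th <- numeric(ms$n_par)
      th[free] <- th_red[seq_len(length(th_red) - n_extra)]
      th[posc] <- t_sd * sqrt(q0)
      rem <- 1 - q0
      if (length(others) == 2L) {
        f <- stats::plogis(extra[2])
        th[poso[[1]]] <- t_sd * sqrt(rem * f)
        th[poso[[2]]] <- t_sd * sqrt(rem * (1 - f))
      } else {
        th[poso[[1]]] <- t_sd * sqrt(rem)
      }
      th
    }
    reduce <- function(theta) {
      tot <- sum(theta[fixed]^2)
      t_sd <- sqrt(tot)
      if (length(others) == 2L) {
        o1 <- theta[poso[[1]]]^2
        o2 <- theta[poso[[2]]]^2
        f <- if (o1 + o2 > 0) o1 / (o1 + o2) else 0.5
        f <- min(max(f, 1e-6), 1 - 1e-6)
        c(theta[free], t_sd, stats::qlogis(f))
      } else {
        c(theta[free], t_sd)
      }
    }
    grad_map <- function(grad_full, th_red, q0) {
      extra <- th_red[seq(length(th_red) - n_extra + 1L, length(th_red))]
      t_sd <- extra[1]
      rem <- 1 - q0
      gt <- sum(grad_full[posc]) * sqrt(q0)
      if (length(others) == 2L) {
        f <- stats::plogis(extra[2])
        gt <- gt + sum(grad_full[poso[[1]]]) * sqrt(rem * f) +
          sum(grad_full[poso[[2]]]) * sqrt(rem * (1 - f))
        gu <- sum(grad_full[poso[[1]]]) * t_sd * sqrt(rem) *
          sqrt(f) * (1 - f) / 2 -
          sum(grad_full[poso[[2]]]) * t_sd * sqrt(rem) *
          sqrt(1 - f) * f / 2
        c(grad_full[free], gt, gu)
      } else {
        gt <- gt + sum(grad_full[poso[[1]]]) * sqrt(rem)
        c(grad_full[free], gt)
      }
    }
    return(list(inject = inject, reduce = reduce, grad_map = grad_map,
                lower = 0, upper = 1))
  }

  stop("profiling is not implemented for quantity '", quantity, "'")
}

#' Profile-likelihood confidence interval for a fitted quantity
#'
#' Re-maximizes the likelihood over all nuisance parameters with the
#' requested quantity held fixed (imposed by reparameterization), and
#' inverts the likelihood-ratio statistic against `qchisq(level, 1)`.
#' Supported quantities: `"rA"`, `"rC"`, `"rE"` on bivariate fits;
#' `"a2"`, `"c2"`, `"e2"` on univariate fits. `method = "wald"` delegates
#' to [wald_ci()].
#'
#' @inheritParams wald_ci
#' @param method `"profile"` (default) or `"wald"`.
#' @param tol bisection tolerance on the quantity scale.
#' @return `c(lower, upper)` with attributes `estimate`, `one_sided`,
#'   `method`.
#' @export
profile_ci <- function(fit, quantity, sex = NULL, level = 0.95,
                       method = c("profile", "wald"), tol = 1e-3) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "twin_fit"))
  if (!isTRUE(fit$converged))
    warning("profiling a fit whose convergence check failed")
  if (method == "wald") return(wald_ci(fit, quantity, sex, level))

  inj <- make_injector(fit, quantity, sex)
  obj <- fit_objective(fit)
  est <- quantity_value(fit$theta, fit$mspec, quantity, sex)

  warm <- new.env(parent = emptyenv())
  warm$start <- inj$reduce(fit$theta)

  prof_fn <- function(q0) {
    fn <- function(th_red) obj$fn(inj$inject(th_red, q0))
    gr <- function(th_red)
      inj$grad_map(obj$gr(inj$inject(th_red, q0)), th_red, q0)
    opt <- stats::optim(warm$start, fn, gr = gr, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-11))
    warm$start <- opt$par
    -opt$value
  }

  ci <- profile_interval(prof_fn, est, fit$logL, level = level,
                         lower = inj$lower, upper = inj$upper,
                         step = 0.02, tol = tol)
  structure(as.numeric(ci), estimate = est,
            one_sided = attr(ci, "one_sided"), method = "profile",
            level = level)
}
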