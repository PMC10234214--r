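#' Fit the thixotropic Herschel-Bulkley model to a steady-shear flow curve
#'
#' Bounded least squares on log-stress residuals (stresses span decades, so
#' the fit weights all rates evenly) using Levenberg-Marquardt with a fixed
#' schedule of eight deterministic starts spread over yield stress,
#' reconstruction timescale and power-law guesses; the start with the lowest
#' residual norm wins, so the fit is fully deterministic given the data.
#' Parameter bounds enforce `sigma0, lam, K >= 0` and `0 < n <= 2`.
#'
#' @param curve Tibble with columns `shear_rate` (1/s) and `stress` (Pa); at
#'   least 6 points spanning at least 1.5 decades of rate.
#' @return An object of class `hb_fit` with the estimates, Jacobian-based
#'   standard errors and 95 percent intervals, residual norm and fitted
#'   values. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' fit <- fit_hb(sim_flow_curve(noise_cv = 0))
#' tidy(fit)
#' @export
fit_hb <- function(curve) {
  stopifnot(all(c("shear_rate", "stress") %in% names(curve)))
  rate <- curve$shear_rate; sigma <- curve$stress
  if (length(rate) < 6) abort("Need at least 6 points to fit the flow model.")
  if (diff(range(log10(rate))) < 1.5) {
    abort("Shear rates must span at least 1.5 decades.")
  }
  if (any(sigma <= 0)) abort("Stresses must be positive.")
  if (sd(log(sigma)) < 1e-10) {
    abort("Fit failure: stress is constant across rates; the flow model is unidentifiable.")
  }

  resid_fn <- function(p) {
    log(hb_stress(rate, p[1], p[2], p[3], p[4])) - log(sigma)
  }

  # deterministic start lattice from data scales
  s_lo <- sigma[which.min(rate)]
  hi <- rate >= stats::median(rate)
  pl <- lm(log(sigma[hi]) ~ log(rate[hi]))
  n0 <- min(max(unname(coef(pl)[2]), 0.1), 1.9)
  K0 <- exp(unname(coef(pl)[1]))
  starts <- purrr::pmap(
    expand.grid(s0 = s_lo * c(0.5, 1), lam = c(0.05, 1), kn = 1:2),
    function(s0, lam, kn) {
      if (kn == 1) c(s0, lam, K0, n0) else c(s0, lam, max(K0 / 2, 1e-3), 0.5)
    })

  best <- run_multistart(resid_fn, starts,
                         lower = c(0, 0, 1e-8, 0.01),
                         upper = c(Inf, Inf, Inf, 2))
  names(best$par) <- c("sigma0", "lam", "K", "n")
  new_rheo_fit("hb_fit", best, data = curve,
               fitted = tibble(shear_rate = rate,
                               stress = hb_stress(rate, best$par[1], best$par[2],
                                                  best$par[3], best$par[4])))
}

#' Fit the fractional Jeffrey model to a frequency sweep
#'
#' Joint bounded least squares on the summed squared log-residuals of both
#' moduli. Internally the model is parameterized as
#' `(log V, log G, alpha, beta/alpha, eta0)` so the order constraint
#' `0 <= beta <= alpha <= 1` becomes a box; eight deterministic starts cover
#' slow/fast relaxation and zero/nonzero dashpot guesses. Standard errors on
#' the natural parameters come from the Jacobian by the delta method.
#'
#' @param sweep Tibble with columns `omega` (rad/s), `g_prime` and
#'   `g_double_prime` (Pa); at least 8 frequencies, both moduli positive.
#' @return An object of class `fjm_fit`; its `fitted` table includes the
#'   loss tangent `tan_delta = G''/G'` at each frequency.
#' @examples
#' fit <- fit_fjm(sim_frequency_sweep(noise_cv = 0))
#' tidy(fit)
#' @export
fit_fjm <- function(sweep) {
  stopifnot(all(c("omega", "g_prime", "g_double_prime") %in% names(sweep)))
  w <- sweep$omega; gp <- sweep$g_prime; gpp <- sweep$g_double_prime
  if (length(w) < 8) abort("Need at least 8 frequencies to fit the viscoelastic model.")
  if (any(gp <= 0) || any(gpp <= 0)) {
    abort("Fit failure: both moduli must be positive at every frequency.")
  }

  to_natural <- function(p) {
    c(V = exp(p[1]), G = exp(p[2]), alpha = p[3], beta = p[3] * p[4], eta0 = p[5])
  }
  resid_fn <- function(p) {
    q <- to_natural(p)
    m <- fjm_moduli(w, q[1], q[2], q[3], q[4], q[5])
    c(log(m$g_prime) - log(gp), log(m$g_double_prime) - log(gpp))
  }

  g_scale <- max(gp)
  eta_guess <- 0.3 * gpp[which.max(w)] / max(w)
  starts <- purrr::pmap(
    expand.grid(alpha = c(0.25, 0.6), u = c(0.15, 0.6), eta = c(0, eta_guess)),
    function(alpha, u, eta) c(log(g_scale), log(g_scale), alpha, u, eta))

  best <- run_multistart(resid_fn, starts,
                         lower = c(-Inf, -Inf, 1e-4, 0, 0),
                         upper = c(Inf, Inf, 1, 1, Inf))
  nat <- to_natural(best$par)
  # delta method: covariance of the natural parameters
  best <- delta_transform(best, to_natural)
  best$par <- nat
  m_fit <- fjm_moduli(w, nat[1], nat[2], nat[3], nat[4], nat[5])
  new_rheo_fit("fjm_fit", best, data = sweep, fitted = m_fit)
}

#' Fit exponential recovery of the storage modulus after flow cessation
#'
#' A thixotropic bioink rebuilds its structure after shear stops; the storage
#' modulus recovers as `G'(t) = g_inf - (g_inf - g0) exp(-t / tau_r)`. Fitted
#' by bounded Levenberg-Marquardt from data-derived starts. A constant trace
#' is returned as `g_inf = g0 = constant` with `tau_r = NA` and
#' `identifiable = FALSE` rather than an arbitrary timescale.
#'
#' @param trace Tibble with columns `time` (s since flow cessation,
#'   non-decreasing from 0) and `g_prime` (Pa); at least 5 points.
#' @return An object of class `recovery_fit` with parameters `g_inf`, `g0`,
#'   `tau_r`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(all(c("time", "g_prime") %in% names(trace)))
  t <- trace$time; g <- trace$g_prime
  if (length(t) < 5) abort("Need at least 5 time points.")
  if (any(t < 0) || is.unsorted(t)) abort("`time` must be non-decreasing from 0.")
  if (sd(g) < 1e-10 * max(abs(mean(g)), 1)) {
    fit <- list(par = c(g_inf = g[1], g0 = g[1], tau_r = NA_real_),
                se = rep(NA_real_, 3), cov = matrix(NA_real_, 3, 3),
                rss = 0, df = NA_integer_, converged = TRUE)
    out <- new_rheo_fit("recovery_fit", fit, data = trace,
                        fitted = tibble(time = t, g_prime = g))
    out$identifiable <- FALSE
    return(out)
  }
  model <- function(p, tt) p[1] - (p[1] - p[2]) * exp(-tt / p[3])
  resid_fn <- function(p) model(p, t) - g
  span <- max(t[length(t)], 1e-6)
  starts <- list(
    c(g[length(g)], g[1], span / 3),
    c(g[length(g)], g[1], span / 10),
    c(max(g), min(g), span),
    c(g[length(g)], g[1], span)
  )
  best <- run_multistart(resid_fn, starts,
                         lower = c(-Inf, -Inf, 1e-9),
                         upper = c(Inf, Inf, Inf))
  names(best$par) <- c("g_inf", "g0", "tau_r")
  out <- new_rheo_fit("recovery_fit", best, data = trace,
                      fitted = tibble(time = t, g_prime = model(best$par, t)))
  out$identifiable <- TRUE
  out
}

#' Critical yield strain from an amplitude sweep
#'
#' The strain at which the storage modulus first drops below
#' `(1 - drop_frac)` of its low-strain plateau, the plateau being the median
#' `G'` over the lowest decade of strain. The crossing is interpolated
#' linearly in log-strain. The criterion is scale invariant: rescaling both
#' moduli leaves the result unchanged.
#'
#' @param sweep Tibble with columns `strain` (dimensionless amplitude,
#'   increasing) and `g_prime` (Pa).
#' @param drop_frac Fractional drop defining yield, in `(0, 0.5]`
#'   (default 0.1).
#' @return One-row tibble: `critical_strain` (`NA` if the material never
#'   yields), `plateau_g_prime`, `yielded`.
#' @export
critical_strain <- function(sweep, drop_frac = 0.1) {
  stopifnot(all(c("strain", "g_prime") %in% names(sweep)))
  if (drop_frac <= 0 || drop_frac > 0.5) abort("`drop_frac` must lie in (0, 0.5].")
  s <- sweep$strain; g <- sweep$g_prime
  if (any(s <= 0)) abort("`strain` must be positive.")
  plateau <- median(g[s <= min(s) * 10])
  target <- (1 - drop_frac) * plateau
  below <- which(g < target)
  if (length(below) == 0) {
    return(tibble(critical_strain = NA_real_, plateau_g_prime = plateau,
                  yielded = FALSE))
  }
  i <- below[1]
  cs <- if (i == 1) s[1] else {
    frac <- (g[i - 1] - target) / (g[i - 1] - g[i])
    exp(log(s[i - 1]) + frac * (log(s[i]) - log(s[i - 1])))
  }
  tibble(critical_strain = cs, plateau_g_prime = plateau, yielded = TRUE)
}

#' Parallel-plate rim-stress correction of a flow curve
#'
#' In plate-plate geometry the shear rate varies across the radius, so the
#' apparent rim stress overestimates the true stress for shear-thinning
#' materials. The standard single-point correction
#' `sigma_true = sigma_apparent (3 + d ln sigma / d ln rate) / 4`
#' is applied with the local log-log slope estimated by central differences
#' (one-sided at the ends). For Newtonian data (slope 1) the factor is
#' exactly 1; for a pure power law of index n it is `(3 + n) / 4`. Already
#' corrected curves are refused.
#'
#' @param curve Tibble with columns `shear_rate` and `stress` (at least 4
#'   points, positive stresses), e.g. from [sim_flow_curve()].
#' @return The curve with corrected `stress` and attribute
#'   `"pp_corrected" = TRUE`.
#' @export
parallel_plate_correct <- function(curve) {
  stopifnot(all(c("shear_rate", "stress") %in% names(curve)))
  if (isTRUE(attr(curve, "pp_corrected"))) {
    abort("Curve is already parallel-plate corrected.")
  }
  if (nrow(curve) < 4) abort("Need at least 4 points for the slope estimate.")
  if (any(curve$stress <= 0)) abort("Stresses must be positive.")
  lx <- log(curve$shear_rate); ly <- log(curve$stress)
  m <- length(lx)
  slope <- numeric(m)
  slope[1] <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  slope[m] <- (ly[m] - ly[m - 1]) / (lx[m] - lx[m - 1])
  if (m > 2) {
    i <- 2:(m - 1)
    slope[i] <- (ly[i + 1] - ly[i - 1]) / (lx[i + 1] - lx[i - 1])
  }
  out <- mutate(curve, stress = .data$stress * (3 + slope) / 4)
  attr(out, "pp_corrected") <- TRUE
  attr(out, "params") <- attr(curve, "params")
  out
}

#' Flag hysteresis between descending and ascending rate sweeps
#'
#' A steady-shear protocol swept down and then back up should retrace itself
#' if the response is truly steady. This compares the two branches pointwise
#' at matching rates and flags a discrepancy when the median relative stress
#' difference exceeds `tol`.
#'
#' @param descending,ascending Tibbles with `shear_rate` and `stress`.
#' @param tol Median relative discrepancy above which hysteresis is flagged.
#' @return One-row tibble: `median_rel_diff`, `hysteresis` (logical),
#'   `n_matched`.
#' @export
check_hysteresis <- function(descending, ascending, tol = 0.1) {
  a <- arrange(descending, .data$shear_rate)
  b <- arrange(ascending, .data$shear_rate)
  matched <- dplyr::inner_join(
    mutate(a, .key = signif(.data$shear_rate, 8)),
    mutate(b, .key = signif(.data$shear_rate, 8)),
    by = ".key", suffix = c("_down", "_up"))
  if (nrow(matched) == 0) abort("No matching shear rates between the branches.")
  rel <- abs(matched$stress_up - matched$stress_down) /
    pmax(abs(matched$stress_down), 1e-12)
  tibble(median_rel_diff = median(rel),
         hysteresis = median(rel) > tol,
         n_matched = nrow(matched))
}

# ---- shared fitting machinery -------------------------------------------

# Levenberg-Marquardt over a fixed list of starts; lowest residual norm wins.
run_multistart <- function(resid_fn, starts, lower, upper) {
  fits <- purrr::map(starts, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("Fit failure: no start converged.")
  rss <- purrr::map_dbl(fits, function(f) sum(f$fvec^2))
  fit <- fits[[which.min(rss)]]
  cov <- fit_covariance(fit)
  list(par = fit$par, rss = sum(fit$fvec^2),
       se = sqrt(pmax(diag(cov), 0)), cov = cov,
       df = length(fit$fvec) - length(fit$par),
       converged = fit$info %in% 1:4,
       n_starts = length(starts))
}

new_rheo_fit <- function(cls, fit, data, fitted) {
  structure(
    list(params = fit$par, se = fit$se, cov = fit$cov, rss = fit$rss,
         df = fit$df, converged = fit$converged, data = data, fitted = fitted),
    class = c(cls, "rheo_fit"))
}

# Covariance from the Gauss-Newton Hessian (J'J) at the optimum.
fit_covariance <- function(fit) {
  p <- length(fit$par)
  m <- length(fit$fvec)
  s2 <- sum(fit$fvec^2) / max(m - p, 1)
  tryCatch(s2 * solve(fit$hessian), error = function(e) matrix(NA_real_, p, p))
}

# Delta-method transform of the parameter covariance under `to_natural`.
delta_transform <- function(best, to_natural) {
  if (all(is.na(best$cov))) {
    best$se <- rep(NA_real_, length(best$par))
    return(best)
  }
  eps <- 1e-6
  p <- best$par
  base <- to_natural(p)
  Jg <- vapply(seq_along(p), function(j) {
    ph <- p; ph[j] <- ph[j] + eps
    (to_natural(ph) - base) / eps
  }, numeric(length(base)))
  covn <- Jg %*% best$cov %*% t(Jg)
  best$cov <- covn
  best$se <- sqrt(pmax(diag(covn), 0))
  best
}
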