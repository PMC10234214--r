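#' Thixotropic Herschel-Bulkley steady-state stress
#'
#' The steady-shear constitutive law for a jammed, thixotropic yield-stress
#' material:
#' \deqn{\sigma(\dot\gamma) = \frac{\sigma_0}{1 + \lambda\dot\gamma} + K\dot\gamma^n}
#' where `sigma0` is the shear-independent intrinsic yield stress of the
#' intact structure, `lam` the timescale of spontaneous structural
#' reconstruction opposing shear-induced breakdown, and `K`, `n` the usual
#' power-law consistency and flow index. With `lam = 0` the classic
#' Herschel-Bulkley law is recovered; positive `lam` makes the steady stress
#' non-monotonic in rate.
#'
#' @param shear_rate Strictly positive shear rates (1/s); vectorized.
#' @param sigma0 Intrinsic yield stress (Pa), `>= 0`.
#' @param lam Thixotropic reconstruction timescale (s), `>= 0`.
#' @param K Consistency (Pa s^n), `>= 0`.
#' @param n Flow index, `0 < n <= 2`.
#' @return Stress in Pa, same length as `shear_rate`.
#' @examples
#' hb_stress(1, sigma0 = 30, lam = 1, K = 10, n = 0.5) # 25 Pa
#' @export
hb_stress <- function(shear_rate, sigma0, lam, K, n) {
  check_hb_params(sigma0, lam, K, n)
  if (any(shear_rate <= 0)) abort("`shear_rate` must be strictly positive.")
  sigma0 / (1 + lam * shear_rate) + K * shear_rate^n
}

#' @rdname hb_stress
#' @return `hb_viscosity()` returns the apparent viscosity `sigma / rate`
#'   (Pa s).
#' @export
hb_viscosity <- function(shear_rate, sigma0, lam, K, n) {
  hb_stress(shear_rate, sigma0, lam, K, n) / shear_rate
}

check_hb_params <- function(sigma0, lam, K, n) {
  if (sigma0 < 0 || lam < 0 || K < 0) abort("`sigma0`, `lam` and `K` must be non-negative.")
  if (n <= 0 || n > 2) abort("`n` must lie in (0, 2].")
  invisible(NULL)
}

# d sigma / d rate of the thixotropic Herschel-Bulkley law.
hb_stress_deriv <- function(shear_rate, sigma0, lam, K, n) {
  -sigma0 * lam / (1 + lam * shear_rate)^2 + n * K * shear_rate^(n - 1)
}

#' Detect non-monotonic steady flow curves
#'
#' A positive reconstruction timescale can make the steady stress decrease
#' then increase with rate. This scans the stress derivative
#' `-sigma0 lam / (1 + lam rate)^2 + n K rate^(n-1)` for sign changes on a
#' log-spaced bracket grid over `rate_window` and refines each bracket by
#' root search; the stress-minimizing rate (derivative crossing from
#' negative to positive) is reported when one exists.
#'
#' @inheritParams hb_stress
#' @param rate_window Length-2 positive rate window (1/s) to examine.
#' @param n_grid Number of bracketing grid points.
#' @return A list: `monotone` (logical), `rate_min` and `stress_min`
#'   (numeric, `NA` when the curve is monotone).
#' @export
hb_flow_monotonicity <- function(sigma0, lam, K, n,
                                 rate_window = c(1e-3, 10), n_grid = 400) {
  check_hb_params(sigma0, lam, K, n)
  stopifnot(length(rate_window) == 2, all(rate_window > 0),
            rate_window[1] < rate_window[2])
  if (lam == 0 || sigma0 == 0 || K == 0) {
    return(list(monotone = TRUE, rate_min = NA_real_, stress_min = NA_real_))
  }
  g <- function(x) hb_stress_deriv(x, sigma0, lam, K, n)
  grid <- exp(seq(log(rate_window[1]), log(rate_window[2]), length.out = n_grid))
  gv <- g(grid)
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  if (length(flips) == 0) {
    return(list(monotone = all(gv >= 0) || all(gv <= 0),
                rate_min = NA_real_, stress_min = NA_real_))
  }
  roots <- vapply(flips, function(i) {
    uniroot(g, lower = grid[i], upper = grid[i + 1], tol = 1e-14)$root
  }, numeric(1))
  minima <- roots[gv[flips] < 0] # derivative crosses - to +
  if (length(minima) == 0) {
    return(list(monotone = FALSE, rate_min = NA_real_, stress_min = NA_real_))
  }
  stresses <- hb_stress(minima, sigma0, lam, K, n)
  best <- which.min(stresses)
  list(monotone = FALSE, rate_min = minima[best], stress_min = stresses[best])
}

#' Fractional Jeffrey storage and loss moduli
#'
#' Complex modulus of two spring-pots in series (quasi-properties `V`, `G`,
#' fractional orders `alpha >= beta`) with a Newtonian dashpot `eta0` in
#' parallel. Writing `Vw = V omega^alpha` and `Gw = G omega^beta`,
#' \deqn{G'(\omega) = \frac{Vw\,Gw^2\cos(\pi\alpha/2) + Vw^2 Gw\cos(\pi\beta/2)}
#'   {Vw^2 + Gw^2 + 2 Vw\,Gw\cos(\pi(\alpha-\beta)/2)}}
#' and likewise for `G''` with sines, plus the additive `eta0 omega` dashpot
#' term in the loss modulus only. These real forms are the algebraic
#' expansion of `G* = G1* G2* / (G1* + G2*) + i omega eta0` with
#' `G1* = V (i omega)^alpha`, `G2* = G (i omega)^beta`.
#'
#' Limits: `alpha = 1, beta = 0, eta0 = 0` is a single-mode Maxwell fluid
#' with relaxation time `V / G`; `alpha = beta` is a single spring-pot with
#' loss tangent `tan(pi alpha / 2)` at every frequency.
#'
#' @param omega Strictly positive angular frequencies (rad/s); vectorized.
#' @param V Quasi-property of the alpha spring-pot (Pa s^alpha), `> 0`.
#' @param G Quasi-property of the beta spring-pot (Pa s^beta), `> 0`.
#' @param alpha,beta Fractional orders with `0 <= beta <= alpha <= 1`.
#' @param eta0 Parallel dashpot viscosity (Pa s), `>= 0`.
#' @return Tibble with columns `omega`, `g_prime`, `g_double_prime` (Pa) and
#'   `tan_delta`.
#' @export
fjm_moduli <- function(omega, V, G, alpha, beta, eta0 = 0) {
  check_fjm_params(V, G, alpha, beta, eta0)
  if (any(omega <= 0)) abort("`omega` must be strictly positive.")
  vw <- V * omega^alpha
  gw <- G * omega^beta
  den <- vw^2 + gw^2 + 2 * vw * gw * cos(pi * (alpha - beta) / 2)
  gp <- (vw * gw^2 * cos(pi * alpha / 2) + vw^2 * gw * cos(pi * beta / 2)) / den
  gpp <- (vw * gw^2 * sin(pi * alpha / 2) + vw^2 * gw * sin(pi * beta / 2)) / den +
    eta0 * omega
  tibble(omega = omega, g_prime = gp, g_double_prime = gpp,
         tan_delta = gpp / gp)
}

check_fjm_params <- function(V, G, alpha, beta, eta0) {
  if (V <= 0 || G <= 0) abort("`V` and `G` must be positive.")
  if (beta < 0 || alpha > 1 || beta > alpha) {
    abort("Fractional orders must satisfy 0 <= beta <= alpha <= 1.")
  }
  if (eta0 < 0) abort("`eta0` must be non-negative.")
  invisible(NULL)
}
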