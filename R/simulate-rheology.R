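#' Simulate a steady-shear flow curve from the thixotropic Herschel-Bulkley model
#'
#' Evaluates the steady-state stress
#' \deqn{\sigma(\dot\gamma) = \frac{\sigma_0}{1 + \lambda\dot\gamma} + K\dot\gamma^n}
#' at each shear rate and multiplies by unit-mean lognormal noise with
#' coefficient of variation `noise_cv` (rheometer error scales with signal).
#' The default parameters describe a jammed aggregate bioink with an intrinsic
#' yield stress of about 30 Pa; the default rate sweep descends from 5 to
#' 0.01 1/s as in a transient-free steady-shear protocol.
#'
#' @param sigma0 Intrinsic yield stress (Pa).
#' @param lam Thixotropic structural-reconstruction timescale (s).
#' @param K Consistency index (Pa s^n).
#' @param n Flow index (dimensionless, 0 < n <= 2).
#' @param shear_rates Strictly positive shear rates (1/s), strictly monotone.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise; must be < 1. `0` gives the noiseless model curve.
#' @param seed Integer seed for the noise; the caller's RNG state is restored.
#' @return A tibble with columns `shear_rate` and `stress` (Pa), carrying the
#'   generating parameters in attribute `"params"` and a `"pp_corrected"`
#'   attribute set to `FALSE`.
#' @examples
#' sim_flow_curve(noise_cv = 0, shear_rates = c(0.1, 1, 5))
#' @export
sim_flow_curve <- function(sigma0 = 29.9, lam = 0.5, K = 8, n = 0.6,
                           shear_rates = exp(seq(log(5), log(0.01), length.out = 20)),
                           noise_cv = 0, seed = 1L) {
  check_abscissa(shear_rates, "shear_rates")
  check_noise_cv(noise_cv)
  mu <- hb_stress(shear_rates, sigma0 = sigma0, lam = lam, K = K, n = n)
  stress <- with_seed(seed, mu * lognormal_factor(length(mu), noise_cv))
  out <- tibble(shear_rate = shear_rates, stress = stress)
  attr(out, "params") <- list(model = "hb_thixo", sigma0 = sigma0, lam = lam,
                              K = K, n = n, noise_cv = noise_cv, seed = seed)
  attr(out, "pp_corrected") <- FALSE
  out
}

#' Simulate an oscillatory frequency sweep from the fractional Jeffrey model
#'
#' Evaluates the storage and loss moduli of the five-parameter fractional
#' Jeffrey model (two spring-pots in series, a Newtonian dashpot in parallel)
#' at each angular frequency and multiplies each modulus by unit-mean
#' lognormal noise of coefficient of variation `noise_cv`. Defaults give a
#' strongly elastic sweep (G' >> G'') over 0.1--10 rad/s, the regime typical
#' of compacted aggregate bioinks.
#'
#' @param V Quasi-property of the alpha spring-pot (Pa s^alpha).
#' @param G Quasi-property of the beta spring-pot (Pa s^beta).
#' @param alpha,beta Fractional orders, `0 <= beta <= alpha <= 1`.
#' @param eta0 Viscosity of the parallel Newtonian dashpot (Pa s).
#' @param omega Strictly positive angular frequencies (rad/s), strictly
#'   monotone.
#' @inheritParams sim_flow_curve
#' @return A tibble with columns `omega`, `g_prime`, `g_double_prime` (Pa)
#'   plus a `"params"` attribute recording the generating parameters and seed.
#' @examples
#' sim_frequency_sweep(noise_cv = 0, omega = c(0.1, 1, 10))
#' @export
sim_frequency_sweep <- function(V = 9000, G = 4000, alpha = 0.30, beta = 0.05,
                                eta0 = 30,
                                omega = exp(seq(log(0.1), log(10), length.out = 16)),
                                noise_cv = 0, seed = 1L) {
  check_abscissa(omega, "omega")
  check_noise_cv(noise_cv)
  mod <- fjm_moduli(omega, V = V, G = G, alpha = alpha, beta = beta, eta0 = eta0)
  out <- with_seed(seed, {
    tibble(
      omega = omega,
      g_prime = mod$g_prime * lognormal_factor(length(omega), noise_cv),
      g_double_prime = mod$g_double_prime * lognormal_factor(length(omega), noise_cv)
    )
  })
  attr(out, "params") <- list(model = "fjm", V = V, G = G, alpha = alpha,
                              beta = beta, eta0 = eta0, noise_cv = noise_cv,
                              seed = seed)
  out
}

# Unit-mean lognormal multipliers with coefficient of variation `cv`.
lognormal_factor <- function(m, cv) {
  if (cv == 0) return(rep(1, m))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(m, mean = -sdlog^2 / 2, sd = sdlog))
}

check_abscissa <- function(x, name) {
  if (any(x <= 0)) abort(sprintf("`%s` must be strictly positive.", name))
  if (length(x) > 1 && !(all(diff(x) > 0) || all(diff(x) < 0))) {
    abort(sprintf("`%s` must be strictly monotone.", name))
  }
  invisible(x)
}

check_noise_cv <- function(cv) {
  if (cv < 0 || cv >= 1) abort("`noise_cv` must lie in [0, 1).")
  invisible(cv)
}
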