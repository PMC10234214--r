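test_that("flow-curve fitting recovers generating parameters", {
  truth <- c(sigma0 = 29.9, lam = 0.5, K = 8, n = 0.6)
  fit <- fit_hb(sim_flow_curve(29.9, 0.5, 8, 0.6, noise_cv = 0))
  expect_true(all(abs(fit$params - truth) / truth < 0.01))
  expect_true(fit$converged)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$term, c("sigma0", "lam", "K", "n"))
  expect_equal(glance(fit)$nobs, 20)

  # nested-model consistency: a lam = 0 curve fits back to lam ~ 0
  fit0 <- fit_hb(sim_flow_curve(30, 0, 10, 0.5, noise_cv = 0))
  expect_lt(fit0$params["lam"], 1e-3)

  flat <- tibble::tibble(shear_rate = 10^seq(-2, 0.7, length.out = 8),
                         stress = rep(50, 8))
  expect_error(fit_hb(flat), "unidentifiable")
  expect_error(fit_hb(sim_flow_curve(shear_rates = c(0.5, 1, 2, 3, 4, 5))),
               "1.5 decades")
})

test_that("frequency-sweep fitting recovers all five parameters", {
  truth <- c(V = 9000, G = 4000, alpha = 0.30, beta = 0.05, eta0 = 30)
  fit <- fit_fjm(sim_frequency_sweep(noise_cv = 0))
  expect_true(all(abs(fit$params - truth) / truth < 0.02))

  # strongly elastic data must fit with tan delta < 1 everywhere
  expect_true(all(fit$fitted$tan_delta < 1))

  # alpha = beta reduces to a single spring-pot: constant loss tangent
  sp <- sim_frequency_sweep(V = 5000, G = 5000, alpha = 0.4, beta = 0.4,
                            eta0 = 0, noise_cv = 0)
  fit_sp <- fit_fjm(sp)
  td <- fit_sp$fitted$tan_delta
  expect_lt(diff(range(td)) / mean(td), 0.01)
  expect_equal(mean(td), tan(pi * 0.4 / 2), tolerance = 0.01)

  bad <- sim_frequency_sweep(noise_cv = 0)
  bad$g_double_prime[3] <- -1
  expect_error(fit_fjm(bad), "positive")
})

test_that("critical strain is found by plateau-drop interpolation", {
  strain <- 10^seq(-4, log10(0.5), length.out = 40)
  g <- ifelse(strain <= 0.03, 1000, 1000 * (strain / 0.03)^-1.5)
  sweep <- tibble::tibble(strain = strain, g_prime = g,
                          g_double_prime = 0.1 * g)
  res <- critical_strain(sweep)
  expect_true(res$yielded)
  expect_lt(abs(res$critical_strain - 0.03) / 0.03, 0.10)

  # scale invariance
  res2 <- critical_strain(dplyr::mutate(sweep, g_prime = g_prime * 37))
  expect_equal(res2$critical_strain, res$critical_strain)

  flat <- tibble::tibble(strain = strain, g_prime = rep(1000, 40))
  expect_false(critical_strain(flat)$yielded)
  expect_error(critical_strain(sweep, drop_frac = 0.9), "drop_frac")
})

test_that("post-flow recovery fitting identifies the exponential rebuild", {
  t <- seq(0, 60, length.out = 25)
  trace <- tibble::tibble(time = t, g_prime = 500 - (500 - 100) * exp(-t / 10))
  fit <- fit_recovery(trace)
  expect_true(all(abs(fit$params - c(500, 100, 10)) / c(500, 100, 10) < 0.01))
  # boundary condition: fitted curve starts at g0
  expect_equal(fit$fitted$g_prime[1], unname(fit$params["g0"]),
               tolerance = 1e-6)

  const <- tibble::tibble(time = t, g_prime = rep(250, 25))
  cf <- fit_recovery(const)
  expect_equal(unname(cf$params["g_inf"]), 250)
  expect_equal(unname(cf$params["g0"]), 250)
  expect_true(is.na(cf$params["tau_r"]))
  expect_false(cf$identifiable)

  expect_error(fit_recovery(trace[1:3, ]), "5 time points")
})

test_that("parallel-plate correction is exact on Newtonian and power-law data", {
  rates <- 10^seq(-2, 0.7, length.out = 12)
  newt <- tibble::tibble(shear_rate = rates, stress = 5 * rates)
  corr <- parallel_plate_correct(newt)
  expect_equal(corr$stress, newt$stress, tolerance = 1e-12)
  expect_true(attr(corr, "pp_corrected"))

  n <- 0.6
  pl <- tibble::tibble(shear_rate = rates, stress = 12 * rates^n)
  corr_pl <- parallel_plate_correct(pl)
  expect_equal(corr_pl$stress / pl$stress, rep((3 + n) / 4, 12),
               tolerance = 0.005)

  expect_error(parallel_plate_correct(corr), "already")
  expect_error(parallel_plate_correct(
    tibble::tibble(shear_rate = rates[1:4], stress = c(1, 2, -3, 4))),
    "positive")
})

test_that("hysteresis between down and up sweeps is flagged at 10%", {
  down <- sim_flow_curve(noise_cv = 0)
  up <- down[nrow(down):1, ]
  same <- check_hysteresis(down, up)
  expect_false(same$hysteresis)
  expect_equal(same$n_matched, 20)

  up2 <- dplyr::mutate(up, stress = stress * 1.25)
  expect_true(check_hysteresis(down, up2)$hysteresis)
})
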