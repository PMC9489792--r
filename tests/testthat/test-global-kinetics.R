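test_that("IRF-convolved exponential matches its limiting forms", {
  t <- seq(-2, 20, 0.05)
  # delta-IRF limit
  expect_equal(exp_conv_irf(5, 0, 0, t),
               ifelse(t >= 0, exp(-t / 5), 0))
  # infinite tau at the IRF center is the half-integrated Gaussian
  expect_equal(exp_conv_irf(Inf, 3, 0.5, 3), 0.5)
  # invalid inputs
  expect_error(exp_conv_irf(-1, 0, 1, t), "tau")
  expect_error(exp_conv_irf(5, 0, -1, t), "sigma")
})

test_that("IRF convolution agrees with adaptive quadrature to 1e-8", {
  cases <- list(c(tau = 40, sigma = 0.08 / 2.3548),
                c(tau = 0.2, sigma = 0.034),
                c(tau = 1e4, sigma = 2))
  for (cs in cases) {
    tau <- cs[["tau"]]; sigma <- cs[["sigma"]]; mu <- 0.1
    t <- seq(mu - 5 * sigma, mu + 20 * max(sigma, min(tau, 100)),
             length.out = 80)
    oracle <- vapply(t, function(ti) {
      if (ti - mu < -12 * sigma) return(0)
      stats::integrate(function(s) stats::dnorm(s, mu, sigma) *
                         exp(-(ti - s) / tau),
                       lower = mu - 12 * sigma,
                       upper = min(ti, mu + 12 * sigma),
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
    }, numeric(1))
    expect_lt(max(abs(exp_conv_irf(tau, mu, sigma, t) - oracle)), 1e-8)
  }
})

test_that("IRF convolution is finite across the stability envelope", {
  t <- seq(-50, 50, 0.5)
  for (tau in c(1e-3, 1, 1e6, 1e9, Inf)) {
    v <- exp_conv_irf(tau, 0, 1, t)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("two-compartment cascade matches the closed form", {
  t <- seq(-1, 200, 0.1)
  sch <- kinetic_scheme(c(4, 40), "sequential", irf_sigma = 0)
  C <- sequential_populations(sch, t)
  k1 <- 1 / 4; k2 <- 1 / 40
  c2 <- ifelse(t >= 0, k1 / (k1 - k2) * (exp(-k2 * t) - exp(-k1 * t)), 0)
  expect_lt(max(abs(C[, 2] - c2)), 1e-10)
})

test_that("five-compartment cascade matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  sch <- quasar2_scheme()
  t <- tas_delay_grid(t_max = 2e4)
  C <- sequential_populations(sch, t)
  k <- c(1 / c(0.183, 4, 40, 288), 0)
  rhs <- function(time, y, parms) {
    inflow <- stats::dnorm(time, 0, 0.034)
    dy <- numeric(5)
    dy[1] <- inflow - k[1] * y[1]
    for (j in 2:5) dy[j] <- k[j - 1] * y[j - 1] - k[j] * y[j]
    list(dy)
  }
  sol <- deSolve::lsoda(rep(0, 5), times = c(min(t) - 0.5, t), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
  Cnum <- sol[-1, -1, drop = FALSE]
  expect_lt(max(abs(C - Cnum)) / max(C), 1e-6)
})

test_that("cascade conserves total population with a terminal component", {
  sch <- quasar2_scheme()
  t_late <- c(1e4, 2e4)
  C <- sequential_populations(sch, t_late)
  expect_equal(rowSums(C), c(1, 1), tolerance = 1e-9)
  # sequential populations stay nonnegative (up to roundoff)
  C_all <- sequential_populations(sch, tas_delay_grid(t_max = 2e4))
  expect_gt(min(C_all), -1e-9)
})

test_that("scheme validation rejects malformed inputs", {
  expect_error(kinetic_scheme(c(Inf, 4)), "terminal")
  expect_error(kinetic_scheme(c(-2, 4)), "> 0")
  expect_error(kinetic_scheme(c(4, 40), "branched"), "branch_fraction")
  expect_error(kinetic_scheme(c(4, 40), "sequential", branch_fraction = 0.1),
               "branched")
  expect_warning(
    sequential_populations(
      kinetic_scheme(c(10, 10 * (1 + 1e-9)), "sequential"), 0:10),
    "near-degenerate")
})

test_that("noise-free global fit round-trips the generator parameters", {
  dat <- quasar2_surface(noise_frac = 0)
  truth <- c(0.183, 4, 40, 288)
  init <- kinetic_scheme(c(truth * 2, Inf), "sequential",
                         irf_center = 0, irf_sigma = 0.034)
  fit <- fit_global(dat, scheme_init = init)
  tau_hat <- fit$scheme$time_constants[1:4]
  expect_lt(max(abs(tau_hat - truth) / truth), 1e-6)
  # EADS match the generator band spectra
  S_true <- attr(dat, "ground_truth")$component_spectra
  expect_lt(max(abs(fit$component_spectra - S_true)), 1e-6)
  # reconstruction identity is exact by construction of the linear solve
  recon <- fit$concentrations %*% fit$component_spectra + fit$residual_matrix
  expect_equal(recon, dat$delta_a, tolerance = 1e-12)
})

test_that("global fit recovers constants within 10% at 1% noise", {
  dat <- quasar2_surface(noise_frac = 0.01, seed = 42)
  fit <- fit_global(dat, n_components = 5, fit_irf = TRUE)
  truth <- c(0.183, 4, 40, 288)
  tau_hat <- fit$scheme$time_constants[1:4]
  expect_lt(max(abs(tau_hat - truth) / truth), 0.10)
  expect_true(fit$convergence$converged)
})

test_that("fit residual matches the injected noise level", {
  sch <- kinetic_scheme(c(40, Inf), "sequential", irf_sigma = 0.034)
  wl <- seq(400, 700, length.out = 80)
  grid <- tas_delay_grid(t_max = 2e3)
  noise_sd <- 0.005
  dat <- simulate_tas(tas_sim_spec(sch, tas_default_bands(2), wl, grid,
                                   noise_sd, seed = 6))
  fit <- fit_global(dat, scheme_init = kinetic_scheme(
    c(60, Inf), "sequential", irf_sigma = 0.034))
  expect_lt(abs(fit$rms_residual - noise_sd) / noise_sd, 0.05)
})

test_that("permuting the initial constants leaves the converged loss alone", {
  dat <- quasar2_surface(noise_frac = 0.01, seed = 11, n_wl = 60)
  i1 <- kinetic_scheme(c(0.3, 6, 30, 400, Inf), "sequential",
                       irf_sigma = 0.034)
  i2 <- kinetic_scheme(c(400, 0.3, 30, 6, Inf), "sequential",
                       irf_sigma = 0.034)
  f1 <- fit_global(dat, scheme_init = i1)
  f2 <- fit_global(dat, scheme_init = i2)
  expect_equal(f1$rms_residual, f2$rms_residual, tolerance = 1e-6)
  expect_equal(f1$scheme$time_constants, f2$scheme$time_constants,
               tolerance = 1e-4)
})

test_that("median constant recovery stays under 5% across seeds", {
  truth <- c(0.183, 4, 40, 288)
  errs <- sapply(1:20, function(s) {
    dat <- quasar2_surface(noise_frac = 0.01, seed = s, n_wl = 60)
    fit <- fit_global(dat, n_components = 5, fit_irf = TRUE)
    abs(fit$scheme$time_constants[1:4] - truth) / truth
  })
  expect_true(all(apply(errs, 1, stats::median) < 0.05))
})

test_that("photoproduct yield estimator hits the branch-fraction limits", {
  init <- kinetic_scheme(c(50, 250, 1800, Inf), "sequential",
                         irf_sigma = 0.034)
  # full ground-state recovery: terminal bleach vanishes
  d0 <- branched_surface(phi = 0)
  f0 <- fit_global(d0, scheme_init = init)
  expect_lt(estimate_photoproduct_yield(f0, 590), 1e-6)
  # no recovery at all
  d1 <- branched_surface(phi = 1)
  f1 <- fit_global(d1, scheme_init = init)
  expect_equal(estimate_photoproduct_yield(f1, 590), 1, tolerance = 0.02)
  expect_error(estimate_photoproduct_yield(f1, 1000), "wavelength")
})

test_that("branched yield is recovered within one point at 1% noise", {
  dat <- branched_surface(phi = 0.04, noise_frac = 0.01, seed = 42)
  fit <- fit_global(dat, n_components = 4, fit_irf = TRUE)
  y <- estimate_photoproduct_yield(fit, 590)
  expect_lt(abs(y - 0.04), 0.01)
})
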