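test_that("fixed seeds give bit-identical generator output", {
  sch <- kinetic_scheme(c(4, Inf), "sequential", irf_sigma = 0.05)
  sp <- tas_sim_spec(sch, tas_default_bands(2), seq(400, 700, 20),
                     tas_delay_grid(t_max = 100, n_lin = 10, n_log = 30),
                     noise_sd = 0.01, seed = 7)
  expect_identical(simulate_tas(sp)$delta_a, simulate_tas(sp)$delta_a)

  ds <- decay_sim_spec(100, 1, noise_model = "poisson", seed = 7)
  expect_identical(simulate_decay_trace(ds)$decay$counts,
                   simulate_decay_trace(ds)$decay$counts)

  cs <- chrom_sim_spec(c(8, 12), c(0.2, 0.2), c(0.3, 0.7),
                       noise_sd = 0.01, seed = 7)
  expect_identical(simulate_chromatogram(cs)$signal,
                   simulate_chromatogram(cs)$signal)

  ts <- titration_sim_spec(9, noise_sd = 0.01, seed = 7)
  expect_identical(simulate_titration(ts)$absorbance,
                   simulate_titration(ts)$absorbance)

  tj <- traj_sim_spec(20, 1, 0.4, 0.6, c(0, 1), geometry_noise = 0.05,
                      seed = 7)
  expect_identical(simulate_trajectory(tj)$coords,
                   simulate_trajectory(tj)$coords)
})

test_that("single-compartment surface reduces to the bare exponential", {
  sch <- kinetic_scheme(10, "sequential", irf_sigma = 0)
  wl <- seq(500, 600, 10)
  t <- c(-1, 0.5, 2, 5, 20)
  sp <- tas_sim_spec(sch, tas_default_bands(1), wl, t, 0, 1)
  d <- simulate_tas(sp)
  S1 <- attr(d, "ground_truth")$component_spectra[1, ]
  expected <- outer(ifelse(t >= 0, exp(-t / 10), 0), S1)
  expect_equal(d$delta_a, expected, tolerance = 1e-12)
})

test_that("noise-free surfaces match their closed form everywhere", {
  sch <- quasar2_scheme()
  wl <- seq(360, 720, length.out = 40)
  grid <- tas_delay_grid(t_max = 2e4)
  d <- simulate_tas(tas_sim_spec(sch, tas_default_bands(5), wl, grid, 0, 1))
  gt <- attr(d, "ground_truth")
  expect_lt(max(abs(d$delta_a - gt$concentrations %*% gt$component_spectra)),
            1e-9)
})

test_that("branch fraction zero recovers the full ground state", {
  d <- branched_surface(phi = 0)
  # terminal-time signal at the bleach center is zero
  j <- which.min(abs(d$wavelengths - 590))
  expect_lt(abs(d$delta_a[nrow(d$delta_a), j]), 1e-9)
})

test_that("decay generator obeys its asymptotics and limits", {
  # tail log-slope approaches the slowest rate
  beta <- c(0.895, 0.04, 0.01, 0.055)
  tau <- c(90, 300, 790, 2850)
  sim <- simulate_decay_trace(decay_sim_spec(tau, beta / tau, irf_fwhm = 120,
                                             noise_model = "none"))
  t <- sim$decay$channel_times; y <- sim$decay$counts
  sel <- t > 12000 & y > 0
  slope <- stats::coef(stats::lm(log(y[sel]) ~ t[sel]))[[2]]
  expect_equal(slope, -1 / 2850, tolerance = 1e-3)
  # all-zero amplitudes: flat zero baseline
  sim0 <- simulate_decay_trace(decay_sim_spec(100, 0, noise_model = "none"))
  expect_true(all(sim0$decay$counts == 0))
  # truncated-window flag
  expect_warning(decay_sim_spec(1e5, 1, noise_model = "none"), "truncated|5x")
})

test_that("chromatogram areas are the requested fractions by construction", {
  cs <- chrom_sim_spec(c(8, 12), c(0.2, 0.2), c(0.21, 0.79))
  ch <- simulate_chromatogram(cs)
  t <- ch$retention_time
  a1 <- sum(diff(t) * (ch$signal[-1] + ch$signal[-length(t)]) / 2 *
              (t[-1] <= 10))
  expect_equal(a1, 0.21, tolerance = 1e-6)
  # single peak integrates to one
  c1 <- simulate_chromatogram(chrom_sim_spec(5, 0.1, 1))
  tt <- c1$retention_time
  expect_equal(sum(diff(tt) * (c1$signal[-1] + c1$signal[-length(tt)]) / 2),
               1, tolerance = 1e-6)
  expect_error(chrom_sim_spec(c(1, 2), c(0.1, 0.1), c(0.5, 0.4)), "sum to 1")
  expect_warning(chrom_sim_spec(c(1, 1.2), c(0.2, 0.2), c(0.5, 0.5)),
                 "overlap")
})

test_that("mean recovered fractions are unbiased across seeds", {
  win <- data.frame(start = c(7, 9.5), end = c(9.4, 13),
                    label = c("a", "b"))
  fr <- sapply(1:50, function(s) {
    cs <- chrom_sim_spec(c(8, 12), c(0.2, 0.2), c(0.47, 0.53),
                         noise_sd = 0.01 * 0.53 / (0.2 * sqrt(2 * pi)),
                         seed = s)
    integrate_isomer_peaks(simulate_chromatogram(cs), win)$fraction
  })
  expect_lt(max(abs(rowMeans(fr) - c(0.47, 0.53))), 0.01)
})

test_that("titration curve hits its midpoint and asymptotes", {
  sp <- titration_sim_spec(9, 1, a_protonated = 1, a_deprotonated = 0.2,
                           ph_grid = c(3, 9, 15))
  a <- simulate_titration(sp)$absorbance
  expect_equal(a[2], (1 + 0.2) / 2, tolerance = 1e-9)   # pH = pKa
  expect_equal(a[1], 1, tolerance = 1e-5)               # pH << pKa
  expect_equal(a[3], 0.2, tolerance = 1e-5)             # pH >> pKa
})

test_that("noisy titrations stay within 3 sigma of the closed form", {
  n_out <- 0
  n_tot <- 0
  for (s in 1:100) {
    sp <- titration_sim_spec(9, 1, 1, 0, seq(5, 11, 0.5),
                             noise_sd = 0.01, seed = s)
    a <- simulate_titration(sp)$absorbance
    truth <- 1 / (1 + 10^(sp$ph_grid - 9))
    n_out <- n_out + sum(abs(a - truth) > 3 * 0.01)
    n_tot <- n_tot + length(a)
  }
  expect_lt(n_out / n_tot, 0.01)
})

test_that("depolarization trace obeys the Hill construction", {
  tr <- simulate_depolarization_trace(4, 2, 1, 2, times = 0:14)
  expect_equal(tr$intensity[1], 1)                       # t = 0
  expect_equal(tr$intensity[tr$time == 4], 1.5)          # half-rise
  expect_true(all(diff(tr$intensity) >= 0))              # monotone
  expect_error(simulate_depolarization_trace(4, -1, 1, 2), "hill_n")
  expect_error(simulate_depolarization_trace(-4, 1, 1, 2), "t_half")
})

test_that("scripted trajectories honor their scripts exactly", {
  # full occupancy, no noise: every frame bonded under the criteria
  tr1 <- simulate_trajectory(traj_sim_spec(50, 1, hbond_occupancy = 1,
                                           inward_fraction = 0, seed = 3))
  hb <- hbond_probability(tr1, "1:N", "1:H", c("2:OD1", "2:OD2"))
  expect_equal(hb$probability, 1)
  # 50/50 flips over 100 frames: exactly 50 inward
  tr2 <- simulate_trajectory(traj_sim_spec(100, 1, 0.5, 0.5, seed = 4))
  or <- classify_side_chain_orientation(tr2, "92:CZ", "95:CG", "204:CD")
  expect_identical(sum(or$class == "inward"), 50L)
  # water counts equal the schedule under the construction radius
  sched <- c(0, 1, 2, 3)
  tr3 <- simulate_trajectory(traj_sim_spec(8, 1, 0.5, 0.5,
                                           water_schedule = sched, seed = 5))
  gt <- attr(tr3, "ground_truth")
  pw <- count_pocket_waters(tr3, gt$pocket_center, gt$pocket_radius)
  expect_identical(pw, gt$water_schedule)
  expect_error(traj_sim_spec(10, 1, hbond_occupancy = 1.2), "occupancy")
})
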