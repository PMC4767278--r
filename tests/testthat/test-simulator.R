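test_that("zero noise, zero coupling, fixed-point start gives a constant field", {
  net <- isolated_network(2)
  sim <- sim_config(n_steps = 300, initial_state = "fixed_point")
  tr <- simulate_trial(net, noise = noise_config(z = 0, seed = 1), sim = sim,
                       keep_units = TRUE)
  expect_equal(max(abs(apply(tr$e_series, 2, function(col) diff(range(col))))),
               0, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical trials; different seeds differ", {
  net <- toy_network_3x3()
  sim <- sim_config(n_steps = 250)
  a <- simulate_trial(net, noise = noise_config(0.05, 42), sim = sim,
                      keep_units = TRUE)
  b <- simulate_trial(net, noise = noise_config(0.05, 42), sim = sim,
                      keep_units = TRUE)
  expect_identical(a$e_series, b$e_series)
  expect_identical(a$mask_mean, b$mask_mean)
  d <- simulate_trial(net, noise = noise_config(0.05, 43), sim = sim)
  expect_false(identical(a$mask_mean, d$mask_mean))
})

test_that("buffered integrator equals the naive full-history reference", {
  net <- toy_network_3x3()
  sim <- sim_config(n_steps = 200)
  mask <- single_unit_mask(3)
  mask[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  drive <- periodic_drive(11, 200)
  for (z in c(0, 0.1)) {
    fast <- simulate_trial(net, noise = noise_config(z, 7), drive = drive,
                           mask = mask, sim = sim, keep_units = TRUE)
    slow <- simulate_trial_reference(net, noise = noise_config(z, 7),
                                     drive = drive, mask = mask, sim = sim)
    expect_lt(max(abs(fast$e_series - slow$e_series)), 1e-12)
    expect_lt(max(abs(fast$mask_mean - slow$mask_mean)), 1e-12)
  }
  # spontaneous case, all-delay-zero variant
  net0 <- assign_delays(net, 0)
  fast <- simulate_trial(net0, noise = noise_config(0.05, 9), sim = sim,
                         keep_units = TRUE)
  slow <- simulate_trial_reference(net0, noise = noise_config(0.05, 9),
                                   sim = sim)
  expect_lt(max(abs(fast$e_series - slow$e_series)), 1e-12)
})

test_that("trajectories stay bounded under default parameters", {
  net <- isolated_network(2)
  sim <- sim_config(n_steps = 5000)
  tr <- simulate_trial(net, noise = noise_config(0.05, 3), sim = sim,
                       keep_units = TRUE)
  expect_true(all(tr$e_series >= -0.1 & tr$e_series <= 1.1))
})

test_that("run_trials: substreams reproduce simulate_trial and stay in (0,1) on average", {
  net <- toy_network_3x3()
  sim <- sim_config(n_steps = 300)
  m <- run_trials(net, 3, base_seed = 17, sim = sim)
  one <- simulate_trial(net,
                        noise = noise_config(0.05,
                                             wcresonance:::derive_seed(17, 1)),
                        sim = sim)
  expect_identical(m[, 1], one$mask_mean)
  expect_false(identical(m[, 1], m[, 2]))
  expect_true(mean(m) > 0 && mean(m) < 1)
})

test_that("mask averaging equals direct matrix computation", {
  net <- toy_network_3x3()
  sim <- sim_config(n_steps = 100)
  tr <- simulate_trial(net, noise = noise_config(0.05, 5), sim = sim,
                       keep_units = TRUE)
  m <- rep(FALSE, 9); m[c(2, 5, 9)] <- TRUE
  expect_equal(mask_average(tr, m),
               tr$e_series %*% (m / sum(m)) |> as.numeric())
  m1 <- rep(FALSE, 9); m1[5] <- TRUE
  expect_equal(mask_average(tr, m1), tr$e_series[, 5])
})

test_that("with zero noise a periodic drive yields a cycle-periodic response", {
  net <- isolated_network(2)
  n_steps <- 2000
  drive <- periodic_drive(10, n_steps)  # 100-step cycles
  mask <- structure(rep(TRUE, 4), side = 2L, class = "wc_mask")
  tr <- simulate_trial(net, noise = noise_config(0, 1), drive = drive,
                       mask = mask, sim = sim_config(n_steps = n_steps))
  x <- tr$mask_mean
  # after a 1 s transient, consecutive cycles coincide
  late <- x[1001:2000]
  dev <- max(abs(late[101:1000] - late[1:900]))
  expect_lt(dev, 1e-6)
})

test_that("halving or doubling the step leaves the driven response peak in place", {
  # the driven steady-state response of a unit stays locked to the drive
  # bin when the integration step is halved or doubled; spontaneous
  # quasi-cycle frequencies, and the oscillating regime of the coupled
  # sheet itself, are step-sensitive at first order (methods vignette)
  net <- isolated_network(2)
  mask <- single_unit_mask(2)
  peak_at_dt <- function(dt) {
    n_steps <- round(2 / dt)  # 2 s duration; 0.5 Hz grid multiple at all dt
    drive <- periodic_drive(12.5, n_steps, dt)
    acc <- 0
    for (k in 1:4) {
      # drop the onset transient so the steady-state response is scored
      tr <- simulate_trial(net, noise = noise_config(0.05, 100 + k),
                           drive = drive, mask = mask,
                           sim = sim_config(dt = dt, n_steps = n_steps,
                                            burn_in = round(0.4 / dt)))
      ps <- power_spectrum(tr$mask_mean, dt)
      acc <- acc + ps$power
    }
    power_spectrum(tr$mask_mean, dt)$freqs[which.max(acc)]
  }
  f1 <- peak_at_dt(0.001)
  expect_lte(abs(peak_at_dt(0.0005) - f1), 0.5)
  expect_lte(abs(peak_at_dt(0.002) - f1), 0.5)
  expect_equal(f1, 12.5)
})

test_that("single-unit spectral peak rises as tau_i falls", {
  net <- isolated_network(2)
  mask <- single_unit_mask(2)
  sim <- sim_config(n_steps = 4000)
  peak_for <- function(tau_i) {
    acc <- 0
    for (k in 1:10) {
      tr <- simulate_trial(net, unit_params(tau_e = 0.018, tau_i = tau_i),
                           noise_config(0.05, 200 + k), mask = mask,
                           sim = sim)
      ps <- power_spectrum(tr$mask_mean)
      acc <- acc + ps$power
    }
    ps$freqs[which.max(acc)]
  }
  expect_gt(peak_for(0.013), peak_for(0.016))
})
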