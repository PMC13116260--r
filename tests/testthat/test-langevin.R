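# BAOAB integrator physics, field protocol, determinism and the reset
# boundary.

test_that("thz_field obeys the protocol contract", {
  p <- field_protocol(amplitude = 0.3, frequency = 1.65, onset = 200,
                      phase = pi / 2)
  expect_identical(thz_field(p, c(0, 100e-12, 199.9e-12)), c(0, 0, 0))
  # peak phase at onset: amplitude 0.3 V/nm -> 3e8 V/m
  expect_equal(thz_field(p, 200e-12), 3e8, tolerance = 1e-12)
  # one period of the 1.65 THz drive is 1/f ~ 0.606 ps
  period <- 1 / 1.65e12
  expect_equal(period * 1e12, 0.606, tolerance = 1e-3)
  expect_equal(thz_field(p, 200e-12 + period), 3e8, tolerance = 1e-6)
  expect_error(field_protocol(amplitude = -1))
  expect_error(field_protocol(amplitude = 1, frequency = 0))
})

test_that("deterministic damped harmonic relaxation at T = 0", {
  k <- 7.14
  r <- baoab_reference("harmonic", k, z0 = 1e-10, v0 = 0, dt = 2.5e-15,
                       nsteps = 2e4, gamma = .mCa * 1e12, mass = .mCa,
                       temperature = 0, stride = 100)
  e <- 0.5 * k * r$z^2 + 0.5 * .mCa * r$v^2
  expect_true(all(diff(e) <= 1e-9 * e[1]))
  expect_lt(abs(r$z[length(r$z)]), 1e-12)   # settled at the minimum
})

test_that("undamped zero-temperature limit conserves energy to O(dt^2)", {
  k <- 7.14
  r <- baoab_reference("harmonic", k, z0 = 1e-10, v0 = 0, dt = 2.5e-15,
                       nsteps = 1e5, gamma = 1e-30, mass = .mCa,
                       temperature = 0, stride = 10)
  e <- 0.5 * k * r$z^2 + 0.5 * .mCa * r$v^2
  expect_lt(max(abs(e - e[1])) / e[1], 1e-2)
})

test_that("thermal harmonic well satisfies equipartition and Maxwell-Boltzmann", {
  k <- 7.14
  T0 <- 310
  set.seed(5)
  r <- baoab_reference("harmonic", k, z0 = 0, v0 = 0, dt = 2.5e-15,
                       nsteps = 2e5, gamma = .mCa * 1e12, mass = .mCa,
                       temperature = T0, stride = 1)
  expect_equal(stats::var(r$z), .kB * T0 / k, tolerance = 0.05)
  ks <- stats::ks.test(r$v, "pnorm", 0, sqrt(.kB * T0 / .mCa))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("free-particle diffusion matches D = kBT/gamma", {
  gam <- .mCa * 1e12
  T0 <- 310
  D <- .kB * T0 / gam
  set.seed(7)
  r <- baoab_reference("free", numeric(), z0 = 0, v0 = 0, dt = 2.5e-15,
                       nsteps = 4e6, gamma = gam, mass = .mCa,
                       temperature = T0, stride = 10)
  # time-averaged MSD at a lag far beyond the momentum relaxation time
  lag <- 4000   # 100 ps at the stored 25 fs stride
  dz <- r$z[-seq_len(lag)] - r$z[seq_len(length(r$z) - lag)]
  msd <- mean(dz^2)
  expect_equal(msd, 2 * D * lag * 25e-15, tolerance = 0.05)
})

test_that("trajectories are reproducible and self-consistent", {
  m <- calibrated_model()
  t1 <- simulate(m, seed = 42, duration = 10e-12)
  t2 <- simulate(m, seed = 42, duration = 10e-12)
  expect_identical(t1$z, t2$z)
  expect_identical(t1$v, t2$v)
  t3 <- simulate(m, seed = 43, duration = 10e-12)
  expect_false(identical(t1$z, t3$z))

  # stored acceleration equals force/mass at the stored samples
  i <- c(10, 500, 3000)
  for (j in i) {
    f <- axial_force(m, t1$z[j, ])
    expect_equal(t1$a[j, ], f / m$ion$mass, tolerance = 1e-10)
  }

  # ions remain bound at the sites over the run
  expect_equal(colMeans(t1$z), c(13.1, 18.2), tolerance = 0.05)
})

test_that("reset boundary relocates a crossing ion and logs the event", {
  m <- calibrated_model()
  geo <- m$geometry
  pars <- cavthz:::.cpp_pars(m, voltage = 0)
  set.seed(9)
  # third ion placed just beyond the exit plane: triggers on the first step
  res <- cavthz:::baoab_channel_run(
    pars, c(13.1, 18.2, geo$exit_z - 0.2) * 1e-10, c(0, 0, -100),
    2.5e-15, 100, m$ion$gamma, m$ion$mass, 310, 0, 1, 0, 0, 1L,
    TRUE, geo$exit_z * 1e-10, geo$res_right[1] * 1e-10,
    geo$res_right[2] * 1e-10, TRUE, 0)
  expect_equal(length(res$event_times), 1L)
  expect_equal(res$event_ion, 3L)
  z3 <- res$z[1, 3] / 1e-10
  expect_gte(z3, geo$res_right[1])
  expect_lte(z3, geo$res_right[2] + 1)

  # counting contract on trajectory objects
  tr <- simulate(m, seed = 3, duration = 5e-12)
  expect_identical(count_permeations(tr), 0L)
  tr$events <- data.frame(time = c(1, 2, 3) * 1e-9, ion = c(1L, 2L, 1L))
  expect_identical(count_permeations(tr), 3L)

  expect_error(simulate(m, seed = 1, duration = 1e-12, boundary = "reset"),
               "n_ions")
})

test_that("resonant drive excites the center of mass; off-resonant does not", {
  m <- calibrated_model()
  ratios <- sapply(c(1.65, 10), function(f) {
    tr <- simulate(m, seed = 31, duration = 300e-12,
                   protocol = field_protocol(0.3, f, onset = 100))
    com <- com_position(tr)
    sd(com[tr$time > 150e-12]) / sd(com[tr$time < 100e-12])
  })
  expect_gt(ratios[1], 3)
  expect_lt(ratios[2], 1.5)
})

test_that("drive-frequency sweep peaks at the intrinsic in-phase mode", {
  m <- calibrated_model()
  freqs <- c(1.0, 1.65, 2.4)
  amp <- sapply(freqs, function(f) {
    tr <- simulate(m, seed = 61, duration = 150e-12,
                   protocol = field_protocol(0.3, f, onset = 20))
    com <- com_position(tr)
    sd(com[tr$time > 50e-12])
  })
  expect_equal(which.max(amp), 2L)
})
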