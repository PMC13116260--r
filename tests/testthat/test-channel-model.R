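# Static force field: Coulomb arithmetic, symmetry, gradients, well
# structure and harmonic calibration aids.

test_that("coulomb energy matches hand arithmetic and basic contracts", {
  # one glutamate charge at 4 A from a +2e test charge, eps 1, no screening:
  # k_e q1 q2 / r = 8.98755e9 * 1.3e-19 * 3.204e-19 / 4e-10 J = 5.84 eV
  m <- channel_model(eps_channel = 1, fixed_screening = Inf)
  m$charges <- data.frame(x = 0, y = 0, z = 0, q = -1.3e-19, label = "E1")
  u <- coulomb_energy(m, c(4, 0, 0))
  expect_equal(u, -5.8419, tolerance = 1e-3)

  # zero test charge: zero energy anywhere
  m2 <- calibrated_model()
  expect_identical(coulomb_energy(m2, c(1, 2, 3), q_test = 0), 0)

  # coincidence with a fixed charge errors, naming the charge
  expect_error(coulomb_energy(m, c(0, 0, 0)), "E1")

  # superposition: energy of the full set equals the sum over single charges
  full <- coulomb_energy(m2, c(0.5, -0.3, 12))
  parts <- vapply(seq_len(nrow(m2$charges)), function(k) {
    mk <- m2
    mk$charges <- m2$charges[k, , drop = FALSE]
    coulomb_energy(mk, c(0.5, -0.3, 12))
  }, numeric(1))
  expect_equal(full, sum(parts), tolerance = 1e-12)
})

test_that("on-axis energy is invariant under azimuthal ring rotation", {
  m <- calibrated_model()
  u0 <- coulomb_energy(m, c(0, 0, 13.5))
  rot <- 37 * pi / 180
  mr <- m
  xy <- cbind(m$charges$x, m$charges$y) %*%
    matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  mr$charges$x <- xy[, 1]; mr$charges$y <- xy[, 2]
  expect_equal(coulomb_energy(mr, c(0, 0, 13.5)), u0, tolerance = 1e-12)
})

test_that("axial potential has the documented well structure", {
  m <- calibrated_model()
  z <- seq(10.5, 19.9, by = 0.01)
  u <- axial_potential(m, z)
  imin <- which(diff(sign(diff(u))) == 2) + 1
  expect_length(imin, 2)
  expect_equal(z[imin], c(14, 18), tolerance = 0.05)  # within 1 A of the rings

  # shallow dipole well near z = -17
  zd <- seq(-20, -14, by = 0.01)
  ud <- axial_potential(m, zd)
  expect_lt(min(ud), -0.2)
  expect_gt(min(ud), -1.0)
  expect_equal(zd[which.min(ud)], -17, tolerance = 0.8)

  # potential decays toward zero away from the charges at zero voltage
  # (the upper reservoir is closer to the rings, so its tail decays slower)
  expect_lt(abs(axial_potential(m, -36)), 0.05)
  uu <- abs(axial_potential(m, c(25, 30, 36)))
  expect_true(all(diff(uu) < 0))
  expect_lt(uu[3], 0.5)

  # a second ion at site 2 pushes the site-1 minimum below 14 A
  u2 <- axial_potential(m, z, other_ion_z = 18.2)
  i2 <- which.min(u2[z < 16])
  expect_lt(z[i2], 14)
})

test_that("forces are the exact negative gradient and obey Newton's 3rd law", {
  m <- calibrated_model()
  # keep outside the 0.5 A ion-ion clamp zone around the partner at 18.2,
  # where the pair potential is deliberately flattened
  zg <- setdiff(seq(11, 20, by = 0.5), c(18, 18.5))
  h <- 1e-4
  fd <- -(axial_potential(m, zg + h) - axial_potential(m, zg - h)) / (2 * h) *
    1.602176634e-19 / 1e-10
  an <- vapply(zg, function(z) axial_force(m, z), numeric(1))
  expect_lt(max(abs(an - fd) / pmax(abs(an), 1e-12)), 1e-6)

  # with voltage and a partner ion
  fd2 <- -(axial_potential(m, zg + h, other_ion_z = 18.2, voltage = -0.4) -
           axial_potential(m, zg - h, other_ion_z = 18.2, voltage = -0.4)) /
    (2 * h) * 1.602176634e-19 / 1e-10
  an2 <- vapply(zg, function(z)
    axial_force(m, c(z, 18.2), voltage = -0.4)[1], numeric(1))
  expect_lt(max(abs(an2 - fd2) / pmax(abs(an2), 1e-12)), 1e-6)

  # ion-ion contributions are equal and opposite: isolate by subtracting
  # the single-ion forces
  f12 <- axial_force(m, c(13.1, 18.2))
  f1 <- axial_force(m, 13.1)
  f2 <- axial_force(m, 18.2)
  expect_equal(f12[1] - f1, -(f12[2] - f2), tolerance = 1e-12)

  # at the two-ion equilibrium the residual force is tiny
  eq <- two_ion_equilibrium(m)
  expect_lt(max(abs(axial_force(m, as.numeric(eq)))), 1e-13)
})

test_that("R and compiled force kernels agree", {
  m <- calibrated_model()
  pars <- cavthz:::.cpp_pars(m, voltage = -0.4)
  z <- c(-30.2, -17, 5.5, 12.7, 16.2, 18.9, 27.3)
  fR <- axial_force(m, z, voltage = -0.4)
  fC <- cavthz:::channel_forces_cpp(pars, z * 1e-10)
  expect_equal(fC, fR, tolerance = 1e-12)
})

test_that("2D potential map is x-mirror symmetric and consistent on axis", {
  m <- calibrated_model()
  x <- seq(-3, 3, by = 0.5)
  z <- seq(11, 20, by = 0.5)
  mp <- potential_map_2d(m, x, z)
  expect_equal(mp$U, mp$U[rev(seq_along(x)), ], tolerance = 1e-12)
  mp0 <- potential_map_2d(m, 0, z)
  expect_equal(as.numeric(mp0$U), axial_potential(m, z), tolerance = 1e-10)
  # on-axis minima of the map sit at the marked binding sites
  zf <- seq(10.5, 19.9, by = 0.01)
  u <- as.numeric(potential_map_2d(m, 0, zf)$U)
  imin <- which(diff(sign(diff(u))) == 2) + 1
  expect_equal(zf[imin], c(14, 18), tolerance = 0.05)
})

test_that("harmonic curvature fit recovers closed-form frequencies", {
  # U = k z^2 / 2 with k = 7.14 N/m -> f = sqrt(k/m)/2pi = 1.651 THz
  k <- 7.14
  pot <- function(z) 0.5 * k * (z * 1e-10)^2 / .eV
  f <- fit_harmonic_curvature(pot, 0, window = 0.4, mass = .mCa)
  expect_equal(as.numeric(f), sqrt(k / .mCa) / (2 * pi) / 1e12,
               tolerance = 1e-6)
  expect_equal(as.numeric(f), 1.651, tolerance = 1e-3)

  # doubling k multiplies f by sqrt(2)
  pot2 <- function(z) 0.5 * 2 * k * (z * 1e-10)^2 / .eV
  f2 <- fit_harmonic_curvature(pot2, 0, window = 0.4, mass = .mCa)
  expect_equal(as.numeric(f2) / as.numeric(f), sqrt(2), tolerance = 1e-6)

  # flat potential: flagged, no silent zero
  expect_error(fit_harmonic_curvature(function(z) 0 * z, 0, window = 0.4,
                                      mass = .mCa), "minimum")
})

test_that("calibrated model reproduces the collective-mode targets", {
  m <- calibrated_model()
  nm <- normal_modes(m)
  expect_equal(nm$freq_THz[1], 1.65, tolerance = 0.05 / 1.65) # 1.65 +/- 0.05
  expect_setequal(nm$labels, c("in-phase", "out-of-phase"))
  expect_equal(nm$positions, c(13.1, 18.2), tolerance = 0.015)
  # static inter-site barrier from the profile
  prof <- potential_profile(m, z = seq(10.5, 19.9, by = 0.02))
  w <- well_minima(prof)
  expect_equal(nrow(w), 2)
  b <- barrier_height(prof, w$position[1], w$position[2])
  expect_equal(as.numeric(b), 0.63, tolerance = 0.02)
})

test_that("model round-trips through a YAML config", {
  m <- calibrated_model()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(ring_radius = 4.0, eps_channel = 2.0), path)
  m2 <- channel_model(config = path)
  expect_equal(m2$ring$radius, 4.0)
  expect_equal(m2$dielectric$eps_channel, 2.0)
  # unspecified entries fall back to the calibrated defaults
  expect_equal(m2$pol$amplitude, m$pol$amplitude)
})
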