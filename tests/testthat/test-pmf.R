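# Boltzmann inversion: Gaussian and uniform oracles, invariances, barrier
# measurement and well location.

test_that("Gaussian samples invert to the analytic quadratic PMF", {
  set.seed(1)
  sigma <- 0.25
  z <- rnorm(4e5, 15, sigma)
  p <- pmf_1d(z, bins = 0.05, temperature = 310)
  kT_eV <- 1.380649e-23 * 310 / .eV
  sel <- p$mask & abs(p$mids - 15) < 2 * sigma
  fit <- stats::lm(p$energy[sel] ~ p$mids[sel] + I(p$mids[sel]^2))
  curv <- 2 * unname(stats::coef(fit)[3])
  expect_equal(curv, kT_eV / sigma^2, tolerance = 0.03)
  # min = 0 convention on occupied bins
  expect_equal(min(p$energy, na.rm = TRUE), 0)
  # temperature consistency: inverting at 2T doubles the curvature
  p2 <- pmf_1d(z, bins = 0.05, temperature = 620)
  fit2 <- stats::lm(p2$energy[sel] ~ p$mids[sel] + I(p$mids[sel]^2))
  expect_equal(2 * unname(stats::coef(fit2)[3]), 2 * curv, tolerance = 0.03)
})

test_that("uniform samples give a flat PMF; duplication leaves it unchanged", {
  set.seed(2)
  z <- runif(2e5, 10, 20)
  p <- pmf_1d(z, bins = 0.25)
  inner <- p$energy[p$mids > 10.5 & p$mids < 19.5]
  expect_lt(max(inner) - min(inner), 0.005)  # eV, sampling noise only
  pdup <- pmf_1d(c(z, z), bins = 0.25)
  expect_equal(pdup$energy, p$energy, tolerance = 1e-12)
  expect_error(pmf_1d(numeric()), "empty")
})

test_that("round trip: sampling exp(-U/kBT) re-recovers a double well", {
  dw <- double_well(depths = c(1, 1), positions = c(-2, 2), curvature = 1)
  zg <- seq(-4, 4, by = 0.01)
  kT_eV <- 1.380649e-23 * 310 / .eV
  # rejection-free sampling from the discretized Boltzmann weight
  set.seed(3)
  w <- exp(-dw(zg) / kT_eV)
  z <- sample(zg, 5e5, replace = TRUE, prob = w) +
    runif(5e5, -0.005, 0.005)
  p <- pmf_1d(z, bins = 0.05, temperature = 310)
  sel <- p$mask
  u_true <- dw(p$mids[sel]) - min(dw(p$mids[sel]))
  expect_lt(stats::median(abs(p$energy[sel] - u_true)), 0.01)
})

test_that("2D inversion reproduces correlated-Gaussian geometry", {
  set.seed(4)
  # correlated displacements: diagonal elongation
  S <- matrix(c(0.04, 0.7 * 0.04, 0.7 * 0.04, 0.04), 2)
  xy <- gaussian2d(S, 3e5, seed = 4)
  p <- pmf_2d(xy[, 1], xy[, 2], bins = 0.02, limits = 0.8)
  expect_identical(p$dim, 2L)
  expect_equal(min(p$energy, na.rm = TRUE), 0)
  # energy rises more slowly along the main diagonal than the anti-diagonal
  d <- seq(0.05, 0.25, by = 0.02)
  u_at <- function(x, y) {
    i <- findInterval(x, p$mids - 0.01); j <- findInterval(y, p$mids2 - 0.01)
    p$energy[cbind(i, j)]
  }
  expect_lt(mean(u_at(d, d), na.rm = TRUE),
            mean(u_at(d, -d), na.rm = TRUE) * 0.5)
  # independent equal variances: circular within noise
  xy0 <- gaussian2d(diag(c(0.04, 0.04)), 3e5, seed = 5)
  p0 <- pmf_2d(xy0[, 1], xy0[, 2], bins = 0.02, limits = 0.8)
  u_at0 <- function(x, y) {
    i <- findInterval(x, p0$mids - 0.01)
    j <- findInterval(y, p0$mids2 - 0.01)
    p0$energy[cbind(i, j)]
  }
  expect_equal(mean(u_at0(d, d), na.rm = TRUE),
               mean(u_at0(d, -d), na.rm = TRUE), tolerance = 0.15)
})

test_that("barrier height measures a constructed double well exactly", {
  dw <- double_well(depths = c(1.5, 1.0), positions = c(-3, 3), curvature = 2)
  z <- seq(-6, 6, by = 0.01)
  p <- cavthz:::new_pmf_grid(z, dw(z) - min(dw(z)), rep(1, length(z)), 310,
                             source = "static")
  w <- well_minima(p)
  expect_equal(w$position, c(-3, 3), tolerance = 0.02)
  b <- barrier_height(p, -3, 3)
  # from the higher (shallower) well to the plateau between the wells
  expect_equal(as.numeric(b), 1.0, tolerance = 0.02)
  expect_false(attr(b, "censored"))
  # kBT companion value at the grid temperature
  expect_equal(attr(b, "kBT"), as.numeric(b) / (1.380649e-23 * 310 / .eV),
               tolerance = 1e-10)
  # monotone profile: zero barrier with a warning
  pm <- cavthz:::new_pmf_grid(z, (z + 5) * 0.1, rep(1, length(z)), 310)
  expect_warning(b0 <- barrier_height(pm, -4, 4), "not separated")
  expect_equal(as.numeric(b0), 0)
})

test_that("masked bins censor the barrier instead of extrapolating", {
  z <- seq(-5, 5, by = 0.1)
  u <- 0.1 * z^2
  u[abs(z) < 1] <- NA   # unsampled top region
  u <- (max(u, na.rm = TRUE) - u)
  u <- u - min(u, na.rm = TRUE)
  p <- cavthz:::new_pmf_grid(z, u, ifelse(is.na(u), 0, 1), 310)
  expect_warning(b <- barrier_height(p, -4, 4), "censored")
  expect_true(attr(b, "censored"))
  expect_gt(as.numeric(b), 0)
})

test_that("calibrated equilibrium run has its wells at the observed sites", {
  trs <- equilibrium_replicates()
  p <- pmf_1d(unlist(lapply(trs, function(t) c(t$z))), bins = 0.1,
              temperature = 310)
  w <- well_minima(p, prominence = 0.05)
  expect_equal(nrow(w), 2L)
  expect_lt(max(abs(w$position - c(13.1, 18.2))), 0.15)
})
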