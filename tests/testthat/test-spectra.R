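# Spectral estimators: FFT amplitude spectra, Welch MSC, the radiative
# coherence enhancement factor, smoothing, replicate statistics, peaks.

make_traj <- function(a1, a2, dt = 2.5e-15) {
  n <- length(a1)
  structure(list(time = seq_len(n) * dt,
                 z = cbind(rep(14, n), rep(18, n)),
                 a = cbind(a1, a2), v = cbind(a1, a2) * 0,
                 events = data.frame(time = numeric(), ion = integer()),
                 config = list(dt = dt, duration = n * dt, temperature = 310,
                               n_ions = 2L, voltage = 0, stride = 1L,
                               boundary = "none", equilibration = 0,
                               seed = NA)),
            class = "ca_trajectory")
}

test_that("pure tone gives a bin-exact peak; zero signal a zero spectrum", {
  dt <- 2.5e-15
  n <- 2^16
  t <- seq_len(n) * dt
  f0 <- 1.65e12
  # align the tone to an exact bin
  f0 <- round(f0 * n * dt) / (n * dt)
  tr <- make_traj(sin(2 * pi * f0 * t), 0 * t)
  sp <- acceleration_spectrum(tr, 1, smooth_sigma = 0)
  expect_equal(sp$freq[which.max(sp$value)], f0 / 1e12, tolerance = 1e-9)
  expect_gt(max(sp$value) / sort(sp$value, decreasing = TRUE)[2], 1e3)
  # amplitude normalization: unit-amplitude tone -> peak amplitude 1
  expect_equal(max(sp$value), 1, tolerance = 1e-6)
  sp0 <- acceleration_spectrum(tr, 2, smooth_sigma = 0)
  expect_true(all(sp0$value == 0))
})

test_that("one-sided amplitude spectrum preserves total power (Parseval)", {
  set.seed(1)
  x <- rnorm(2^14)
  tr <- make_traj(x, x)
  sp <- acceleration_spectrum(tr, 1, smooth_sigma = 0)
  # sum of amp^2/2 over one-sided bins = mean squared signal (mean removed)
  expect_equal(sum(sp$value^2) / 2, mean((x - mean(x))^2),
               tolerance = 1e-3)  # edge bins (DC/Nyquist) carry the residual
})

test_that("distance spectrum cancels in-phase motion, keeps anti-phase", {
  osc_in <- oscillator_pair(amp_in = 1e14, amp_out = 0, duration = 100e-12)
  spd <- distance_spectrum(osc_in, smooth_sigma = 0)
  expect_lt(max(spd$value), 1e-10)
  osc_out <- oscillator_pair(amp_in = 0, amp_out = 1e14, duration = 100e-12)
  spd2 <- distance_spectrum(osc_out, smooth_sigma = 0)
  expect_equal(spd2$freq[which.max(spd2$value)], 2.84, tolerance = 0.02)
  tr3 <- make_traj(1:10, 1:10)
  tr3$z <- cbind(tr3$z, tr3$z[, 1])
  expect_error(distance_spectrum(tr3), "2-ion")
})

test_that("MSC is 1 for linearly dependent signals and in [0,1] always", {
  set.seed(2)
  x <- rnorm(2^14)
  m <- msc(x, 3 * x, dt = 1e-14)
  powered <- m$freq > 0
  expect_true(all(m$value[powered] > 1 - 1e-9))
  expect_true(all(m$value >= 0 & m$value <= 1))
})

test_that("independent white noise MSC sits at the 1/segments bias level", {
  set.seed(3)
  n <- 2^16
  m <- msc(rnorm(n), rnorm(n), dt = 1e-14, n_segments = 64)
  mean_msc <- mean(m$value[-1])
  expect_lt(mean_msc, 0.2)
  # known estimator bias ~ 1/(number of averaged segments)
  expect_equal(mean_msc, 1 / m$estimator$n_segments, tolerance = 0.5)
})

test_that("MSC refuses a single unaveraged segment", {
  expect_error(msc(rnorm(64), rnorm(64), dt = 1, n_segments = 1),
               "identically 1")
})

test_that("coherence factor hits its limiting values", {
  set.seed(4)
  a <- rnorm(2^14)
  expect_gt(min(coherence_factor(a, a, dt = 1e-14)$value, na.rm = TRUE),
            2 - 1e-9)
  expect_lt(max(coherence_factor(a, -a, dt = 1e-14)$value, na.rm = TRUE),
            1e-9)
  b <- rnorm(2^14)
  alpha <- coherence_factor(a, b, dt = 1e-14, n_segments = 64)
  expect_equal(mean(alpha$value, na.rm = TRUE), 1, tolerance = 0.1)
})

test_that("MSC and alpha are invariant under common rescaling", {
  set.seed(5)
  a <- rnorm(2^13); b <- rnorm(2^13) + 0.5 * a
  m1 <- msc(a, b, dt = 1e-14)
  m2 <- msc(10 * a, 10 * b, dt = 1e-14)
  expect_equal(m1$value, m2$value, tolerance = 1e-9)
  c1 <- coherence_factor(a, b, dt = 1e-14)
  c2 <- coherence_factor(10 * a, 10 * b, dt = 1e-14)
  expect_equal(c1$value, c2$value, tolerance = 1e-9)
})

test_that("gaussian smoothing: identity, delta response, level preservation", {
  x <- rnorm(200)
  expect_identical(gaussian_smooth(x, 0), x)
  d <- c(rep(0, 100), 1, rep(0, 100))
  s <- gaussian_smooth(d, 5)
  expect_equal(sum(s), 1, tolerance = 1e-3)           # integral preserved
  expect_equal(which.max(s), 101)
  fit <- stats::sd(rep(seq_along(d), round(s * 1e6)))  # empirical width
  expect_equal(fit, 5, tolerance = 0.02)
  w <- rep(2.5, 300)
  expect_equal(gaussian_smooth(w, 4), w, tolerance = 1e-9)
})

test_that("replicate statistics aggregate pointwise", {
  f <- seq(0.1, 5, by = 0.1)
  mk <- function(v) cavthz:::new_spectrum_set(f, v, "amplitude")
  same <- replicate_stats(list(mk(f), mk(f), mk(f)))
  expect_true(all(same$sd == 0))
  two <- replicate_stats(list(mk(rep(0, length(f))), mk(rep(2, length(f)))))
  expect_true(all(two$value == 1))
  expect_true(all(abs(two$sd - sqrt(2)) < 1e-12))
  expect_error(replicate_stats(list(mk(f), cavthz:::new_spectrum_set(f[-1], f[-1], "amplitude"))),
               "grids")
})

test_that("peak finding: detection, monotone input, separation tie rule", {
  f <- seq(0, 5, by = 0.01)
  y <- exp(-(f - 1.65)^2 / 0.02) + 0.6 * exp(-(f - 2.84)^2 / 0.02)
  sp <- cavthz:::new_spectrum_set(f, y, "amplitude")
  pk <- find_peaks(sp, prominence = 0.1)
  expect_equal(sort(pk$frequency), c(1.65, 2.84), tolerance = 0.01)
  expect_identical(nrow(find_peaks(cavthz:::new_spectrum_set(f, f, "amplitude"),
                                   prominence = 0.1)), 0L)
  # two close peaks: the taller is kept
  y2 <- exp(-(f - 2.0)^2 / 0.005) + 0.8 * exp(-(f - 2.2)^2 / 0.005)
  pk2 <- find_peaks(cavthz:::new_spectrum_set(f, y2, "amplitude"),
                    prominence = 0.05, min_sep = 0.5)
  expect_identical(nrow(pk2), 1L)
  expect_equal(pk2$frequency, 2.0, tolerance = 0.01)
})

test_that("Welch MSC agrees with the smoothed-periodogram estimator", {
  # independent route: stats::spec.pgram Daniell-smoothed squared coherency
  set.seed(8)
  n <- 2^14
  sh <- stats::filter(rnorm(n + 10), rep(1, 5))[6:(n + 5)]
  x <- as.numeric(sh) + rnorm(n)
  y <- as.numeric(sh) + rnorm(n)
  m <- msc(x, y, dt = 1, n_segments = 32)
  sp <- stats::spec.pgram(cbind(x, y), spans = c(31, 31), taper = 0.1,
                          plot = FALSE, detrend = TRUE)
  # compare coarse band averages of the two estimates
  band <- function(f, v, lo, hi) mean(v[f >= lo & f < hi], na.rm = TRUE)
  for (b in list(c(0.01, 0.1), c(0.1, 0.25), c(0.25, 0.45))) {
    expect_equal(band(m$freq * 1e12, m$value, b[1], b[2]),
                 band(sp$freq, sp$coh, b[1], b[2]), tolerance = 0.15)
  }
})
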