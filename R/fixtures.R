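# Synthetic fixtures with known ground truth, mirroring the statistical
# structure the analysis stages assume: two-mode coherent oscillator pairs,
# Gaussian equilibrium densities, toy double wells, Poisson event counts.
# Every fixture is deterministic for a fixed seed.

#' Synthetic two-mode oscillator pair
#'
#' Builds a pair of signals with an in-phase component at `f_in` (same sign
#' in both) and an out-of-phase component at `f_out` (opposite signs), plus
#' optional white noise:
#' `a_i(t) = amp_in sin(2 pi f_in t) +/- amp_out sin(2 pi f_out t) + noise`.
#' Velocities and positions follow by analytic integration, so the object
#' can stand in for a 2-ion trajectory in the spectral and PMF stages.
#'
#' @param f_in,f_out Mode frequencies, THz.
#' @param amp_in,amp_out Acceleration amplitudes, m/s^2. The default 1e14
#'   m/s^2 corresponds to sub-angstrom displacement amplitudes at THz
#'   frequencies, the scale of the confined-ion oscillations.
#' @param noise_sd White-noise SD added to the accelerations, m/s^2.
#' @param dt Sampling interval, s (must resolve both frequencies).
#' @param duration Total duration, s.
#' @param centers Mean positions of the two "ions", angstrom.
#' @param temperature Nominal temperature stored in the metadata, K.
#' @param seed RNG seed.
#' @return A `ca_trajectory` with `time`, `z` (A), `v`, `a` and metadata.
#' @export
oscillator_pair <- function(f_in = 1.65, f_out = 2.84, amp_in = 1e14,
                            amp_out = 1e14, noise_sd = 0, dt = 2.5e-15,
                            duration = 400e-12, centers = c(14, 18),
                            temperature = 310, seed = NULL) {
  w_in <- 2 * pi * f_in * .const$THz
  w_out <- 2 * pi * f_out * .const$THz
  if (1 / (2 * dt) <= max(f_in, f_out) * .const$THz)
    stop("Nyquist violation: dt does not resolve the requested frequencies")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(dt, duration, by = dt)
  s_in <- sin(w_in * t); s_out <- sin(w_out * t)
  a1 <- amp_in * s_in + amp_out * s_out
  a2 <- amp_in * s_in - amp_out * s_out
  n1 <- n2 <- 0
  if (noise_sd > 0) {
    n1 <- stats::rnorm(length(t), 0, noise_sd)
    n2 <- stats::rnorm(length(t), 0, noise_sd)
    a1 <- a1 + n1
    a2 <- a2 + n2
  }
  # analytic integrals of the tones; the noise is integrated numerically
  v_in <- -amp_in / w_in * cos(w_in * t)
  v_out <- -amp_out / w_out * cos(w_out * t)
  z_in <- -amp_in / w_in^2 * s_in
  z_out <- -amp_out / w_out^2 * s_out
  vn1 <- cumsum(n1) * dt
  vn2 <- cumsum(n2) * dt
  z <- cbind(centers[1] + (z_in + z_out + cumsum(vn1) * dt) / .const$ang,
             centers[2] + (z_in - z_out + cumsum(vn2) * dt) / .const$ang)
  v <- cbind(v_in + v_out + vn1, v_in - v_out + vn2)
  structure(list(
    time = t, z = z, v = v, a = cbind(a1, a2),
    events = data.frame(time = numeric(), ion = integer()),
    config = list(dt = dt, duration = duration, temperature = temperature,
                  n_ions = 2L, voltage = 0, stride = 1L, boundary = "none",
                  equilibration = 0, seed = seed),
    protocol = NULL, seed = seed, synthetic = "oscillator_pair"
  ), class = "ca_trajectory")
}

#' Bivariate Gaussian displacement samples
#'
#' I.i.d. samples from a centered bivariate normal with the given covariance;
#' the analytic PMF is the quadratic form `kB T / 2 * x' Sigma^-1 x`, so the
#' output is the exact oracle input for [pmf_2d()] and the eigensolver
#' round-trip.
#'
#' @param cov 2x2 positive-definite covariance, in square angstrom.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return `n` x 2 matrix of displacements (angstrom).
#' @export
gaussian2d <- function(cov, n, seed = NULL) {
  stopifnot(all(dim(cov) == c(2, 2)))
  L <- tryCatch(chol(cov),
                error = function(e) stop("covariance is not positive definite"))
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(2 * n), n, 2) %*% L
}

#' Covariance whose quadratic PMF has given mode frequencies
#'
#' In the rotated coordinates `s = (dz1+dz2)/sqrt(2)`, `a = (dz1-dz2)/sqrt(2)`
#' a harmonic landscape with frequencies `f_in`, `f_out` has equilibrium
#' variances `sigma^2 = kB T / (m (2 pi f)^2)`; rotating back gives the
#' displacement covariance.
#'
#' @param f_in,f_out Mode frequencies, THz.
#' @param temperature Temperature, K.
#' @param mass Ion mass, kg.
#' @return 2x2 covariance matrix in square angstrom.
#' @export
cov_from_modes <- function(f_in = 1.65, f_out = 2.84, temperature = 310,
                           mass = .ca_mass) {
  var_s <- kBT(temperature) / (mass * (2 * pi * f_in * .const$THz)^2)
  var_a <- kBT(temperature) / (mass * (2 * pi * f_out * .const$THz)^2)
  R <- matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)
  (R %*% diag(c(var_s, var_a)) %*% t(R)) / .const$ang^2
}

#' Toy double-well potential
#'
#' Smooth 1D two-well potential built from two downward Gaussians on a zero
#' baseline: well `i` has depth `depths[i]` (eV) at `positions[i]` (A) and
#' bottom curvature `curvature` (eV/A^2), so for well-separated wells the
#' barrier from the shallower well to the plateau is its depth.
#'
#' @param depths Two well depths, eV (positive).
#' @param positions Two well positions, angstrom (distinct).
#' @param curvature Curvature at each well bottom, eV/A^2.
#' @return A function `z -> energy (eV)` with attributes `depths`,
#'   `positions`, `widths`.
#' @export
double_well <- function(depths = c(1, 1), positions = c(-2, 2),
                        curvature = 1) {
  stopifnot(length(depths) == 2, length(positions) == 2,
            positions[1] != positions[2], all(depths > 0), curvature > 0)
  w <- sqrt(depths / curvature)   # depth/width^2 = curvature
  f <- function(z) {
    -depths[1] * exp(-(z - positions[1])^2 / (2 * w[1]^2)) -
      depths[2] * exp(-(z - positions[2])^2 / (2 * w[2]^2))
  }
  structure(f, depths = depths, positions = positions, widths = w)
}

#' Poisson-distributed event counts
#'
#' @param rate Expected events per trajectory.
#' @param n_traj Number of trajectories.
#' @param seed RNG seed.
#' @return Integer vector of counts.
#' @export
poisson_counts <- function(rate, n_traj, seed = NULL) {
  stopifnot(rate >= 0, n_traj >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(n_traj, rate)
}
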