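# Frequency-domain characterization of ion trajectories: amplitude spectra,
# Welch cross-spectral estimates, magnitude-squared coherence, and the
# radiative coherence enhancement factor.

new_spectrum_set <- function(freq, value, kind, label = "", smooth = NULL,
                             mean = NULL, sd = NULL, extra = list(),
                             estimator = list()) {
  stopifnot(all(diff(freq) > 0), is.null(smooth) || length(smooth) == length(value))
  structure(list(freq = freq, value = value, smooth = smooth, kind = kind,
                 label = label, mean = mean, sd = sd, extra = extra,
                 estimator = estimator),
            class = "spectrum_set")
}

.check_uniform_time <- function(t) {
  dt <- diff(t)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stop("time grid is not uniform; spectra require uniform sampling")
  stats::median(dt)
}

# one-sided amplitude spectrum of a mean-removed series; freq in THz
.amplitude_spectrum <- function(x, dt) {
  x <- x - mean(x)
  n <- length(x)
  nf <- floor(n / 2)
  amp <- (2 / n) * Mod(stats::fft(x))[seq_len(nf)]
  freq <- (seq_len(nf) - 1) / (n * dt) / .const$THz
  list(freq = freq, amp = amp)
}

#' Amplitude spectrum of the axial acceleration
#'
#' One-sided FFT amplitude of an ion's mean-removed axial acceleration. For
#' the calibrated equilibrium pair the spectrum shows the two collective
#' modes near 1.65 and 2.84 THz.
#'
#' @param traj A `ca_trajectory` with stored samples on a uniform time grid.
#' @param ion Ion index.
#' @param smooth_sigma Gaussian smoothing width in THz (0 = none).
#' @return A `spectrum_set` (kind `"amplitude"`) with the raw and smoothed
#'   spectrum.
#' @export
acceleration_spectrum <- function(traj, ion = 1, smooth_sigma = 0.05) {
  stopifnot(inherits(traj, "ca_trajectory"), !is.null(traj$a))
  dt <- .check_uniform_time(traj$time)
  s <- .amplitude_spectrum(traj$a[, ion], dt)
  out <- new_spectrum_set(s$freq, s$amp, "amplitude",
                          label = sprintf("acceleration, ion %d", ion))
  out$smooth <- gaussian_smooth(out, smooth_sigma)$value
  out
}

#' Amplitude spectrum of the inter-ionic distance
#'
#' FFT amplitude of `|z1 - z2|` after mean removal. In-phase motion cancels
#' in the distance, so only the out-of-phase collective mode appears.
#'
#' @inheritParams acceleration_spectrum
#' @return A `spectrum_set` (kind `"amplitude"`).
#' @export
distance_spectrum <- function(traj, smooth_sigma = 0.05) {
  stopifnot(inherits(traj, "ca_trajectory"), !is.null(traj$z))
  if (ncol(traj$z) != 2)
    stop("distance spectrum is defined for a 2-ion trajectory")
  dt <- .check_uniform_time(traj$time)
  s <- .amplitude_spectrum(abs(traj$z[, 1] - traj$z[, 2]) * .const$ang, dt)
  out <- new_spectrum_set(s$freq, s$amp, "amplitude", label = "|z1 - z2|")
  out$smooth <- gaussian_smooth(out, smooth_sigma)$value
  out
}

# Welch segment-averaged windowed periodograms; returns one-sided auto and
# cross spectral densities on the segment frequency grid (Hz).
.welch <- function(x, y = NULL, dt, n_segments = 16, overlap = 0.5) {
  n <- length(x)
  L <- floor(n / n_segments)
  if (L < 8) stop("series too short for the requested segmentation")
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  if (length(starts) < 2)
    stop("fewer than 2 Welch segments: the magnitude-squared coherence of a ",
         "single unaveraged segment is identically 1; use more/shorter segments")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))   # Hann
  norm <- sum(w^2)
  nf <- floor(L / 2)
  Pxx <- numeric(nf); Pyy <- numeric(nf); Pxy <- complex(nf)
  for (s0 in starts) {
    xs <- x[s0:(s0 + L - 1)]; xs <- (xs - mean(xs)) * w
    X <- stats::fft(xs)[seq_len(nf)]
    Pxx <- Pxx + Re(X * Conj(X))
    if (!is.null(y)) {
      ys <- y[s0:(s0 + L - 1)]; ys <- (ys - mean(ys)) * w
      Y <- stats::fft(ys)[seq_len(nf)]
      Pyy <- Pyy + Re(Y * Conj(Y))
      Pxy <- Pxy + X * Conj(Y)
    }
  }
  m <- length(starts)
  scale <- 2 * dt / (norm * m)
  list(freq = (seq_len(nf) - 1) / (L * dt),
       Pxx = Pxx * scale, Pyy = Pyy * scale, Pxy = Pxy * scale,
       n_segments = m, segment_length = L)
}

#' Magnitude-squared coherence of two signals
#'
#' Welch estimate of `C12(f) = |P12|^2 / (P11 P22)`, the frequency-resolved
#' squared linear correlation of two series, in `[0, 1]`. Cross- and
#' auto-spectra are segment-averaged windowed (Hann, 50% overlap)
#' periodograms; at least two segments are required (the single-segment MSC
#' is identically 1).
#'
#' @param v1,v2 Equal-length numeric series (e.g. the two ions' axial
#'   velocities), or a 2-ion `ca_trajectory` as `v1` (velocities are used).
#' @param dt Sampling interval in seconds (taken from the trajectory if one
#'   is given).
#' @param n_segments Nominal number of non-overlapping segments the series is
#'   split into (with 50% overlap the averaged count is about twice this).
#' @param overlap Segment overlap fraction.
#' @return A `spectrum_set` (kind `"msc"`), frequency in THz.
#' @export
msc <- function(v1, v2 = NULL, dt = NULL, n_segments = 16, overlap = 0.5) {
  if (inherits(v1, "ca_trajectory")) {
    stopifnot(ncol(v1$v) == 2)
    dt <- .check_uniform_time(v1$time)
    v2 <- v1$v[, 2]
    v1 <- v1$v[, 1]
  }
  stopifnot(length(v1) == length(v2), !is.null(dt))
  w <- .welch(v1, v2, dt, n_segments, overlap)
  C <- Mod(w$Pxy)^2 / pmax(w$Pxx * w$Pyy, .Machine$double.xmin)
  C <- pmin(pmax(C, 0), 1)
  new_spectrum_set(w$freq / .const$THz, C, "msc",
                   label = "magnitude-squared coherence",
                   estimator = w[c("n_segments", "segment_length")])
}

#' Radiative coherence enhancement factor
#'
#' Spectrum of the coherent radiated power `S_coh(f)` (power spectral density
#' of the summed accelerations), the incoherent power `S_incoh(f)` (sum of
#' the individual densities), and their ratio `alpha = S_coh / S_incoh`:
#' 2 for identical accelerations (in-phase), 0 for equal-and-opposite
#' (out-of-phase), 1 for unrelated motion. `alpha` is reported only where
#' `S_incoh` exceeds a noise floor and is `NA` elsewhere.
#'
#' @param a1,a2 Equal-length acceleration series, or a 2-ion `ca_trajectory`
#'   as `a1`.
#' @inheritParams msc
#' @param floor_frac Noise floor as a fraction of the peak incoherent power.
#' @return A `spectrum_set` (kind `"alpha"`) whose `value` is alpha and whose
#'   `extra` carries `S_coh` and `S_incoh`.
#' @export
coherence_factor <- function(a1, a2 = NULL, dt = NULL, n_segments = 16,
                             overlap = 0.5, floor_frac = 1e-9) {
  if (inherits(a1, "ca_trajectory")) {
    stopifnot(ncol(a1$a) == 2)
    dt <- .check_uniform_time(a1$time)
    a2 <- a1$a[, 2]
    a1 <- a1$a[, 1]
  }
  stopifnot(length(a1) == length(a2), !is.null(dt))
  wc <- .welch(a1 + a2, NULL, dt, n_segments, overlap)
  w1 <- .welch(a1, NULL, dt, n_segments, overlap)
  w2 <- .welch(a2, NULL, dt, n_segments, overlap)
  S_coh <- wc$Pxx
  S_incoh <- w1$Pxx + w2$Pxx
  alpha <- ifelse(S_incoh > floor_frac * max(S_incoh),
                  S_coh / S_incoh, NA_real_)
  alpha <- pmin(pmax(alpha, 0), 2)
  new_spectrum_set(wc$freq / .const$THz, alpha, "alpha",
                   label = "radiative coherence enhancement factor",
                   extra = list(S_coh = S_coh, S_incoh = S_incoh),
                   estimator = wc[c("n_segments", "segment_length")])
}

#' Gaussian smoothing of a spectrum
#'
#' Convolution with a unit-area Gaussian kernel; near the edges the truncated
#' kernel is renormalized so the total integral is preserved.
#'
#' @param spectrum A `spectrum_set` or numeric vector.
#' @param sigma Kernel width in THz (for a `spectrum_set`) or in bins (for a
#'   bare vector). `0` returns the input unchanged.
#' @return Same type as the input, smoothed.
#' @export
gaussian_smooth <- function(spectrum, sigma) {
  stopifnot(sigma >= 0)
  if (inherits(spectrum, "spectrum_set")) {
    df <- spectrum$freq[2] - spectrum$freq[1]
    out <- spectrum
    out$value <- gaussian_smooth(spectrum$value, sigma / df)
    return(out)
  }
  x <- spectrum
  if (sigma == 0 || length(x) < 2) return(x)
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, kern, sides = 2)[(half + 1):(half + n)]
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  wt <- stats::filter(wp, kern, sides = 2)[(half + 1):(half + n)]
  as.numeric(sm / wt)
}

#' Pointwise replicate mean and standard deviation of spectra
#'
#' @param spectra A list of `spectrum_set` objects on identical frequency
#'   grids (e.g. from independent simulation replicates).
#' @return A `spectrum_set` whose `value`/`mean` is the pointwise mean and
#'   whose `sd` is the pointwise sample standard deviation.
#' @export
replicate_stats <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "spectrum_set")))
  f0 <- spectra[[1]]$freq
  for (s in spectra)
    if (length(s$freq) != length(f0) || any(abs(s$freq - f0) > 1e-9))
      stop("replicate spectra are on different frequency grids")
  M <- vapply(spectra, `[[`, numeric(length(f0)), "value")
  m <- rowMeans(M)
  sd <- if (ncol(M) > 1) apply(M, 1, stats::sd) else rep(0, length(f0))
  out <- spectra[[1]]
  out$value <- m
  out$mean <- m
  out$sd <- sd
  out$smooth <- NULL
  out$label <- paste0(out$label, sprintf(" (mean of %d replicates)", ncol(M)))
  out
}

#' Locate spectral peaks
#'
#' Local maxima above a prominence threshold, separated by a minimum
#' frequency distance (the taller of two close peaks is kept), sorted by
#' height.
#'
#' @param spectrum A `spectrum_set` (the smoothed curve is used when
#'   available) or numeric vector with a `freq` attribute.
#' @param prominence Minimum height of a peak above the higher of its
#'   flanking valleys (same units as the spectrum).
#' @param min_sep Minimum separation in THz.
#' @return `data.frame(frequency, height)` sorted by decreasing height (may
#'   be empty).
#' @export
find_peaks <- function(spectrum, prominence = 0, min_sep = 0) {
  if (inherits(spectrum, "spectrum_set")) {
    y <- if (!is.null(spectrum$smooth)) spectrum$smooth else spectrum$value
    f <- spectrum$freq
  } else {
    y <- as.numeric(spectrum)
    f <- seq_along(y)
  }
  ok <- is.finite(y)
  y[!ok] <- -Inf
  n <- length(y)
  if (n < 3) return(data.frame(frequency = numeric(), height = numeric()))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lmin <- y[i]; j <- i
    while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
    rmin <- y[i]; j <- i
    while (j < n && y[j + 1] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
    keep[k] <- is.finite(y[i]) && (y[i] - max(lmin, rmin)) >= prominence
  }
  idx <- idx[keep]
  pk <- data.frame(frequency = f[idx], height = y[idx])
  pk <- pk[order(-pk$height), , drop = FALSE]
  if (min_sep > 0 && nrow(pk) > 1) {
    sel <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))) {
      if (!sel[i]) next
      close <- which(sel & abs(pk$frequency - pk$frequency[i]) < min_sep)
      close <- setdiff(close, seq_len(i))
      sel[close] <- FALSE
    }
    pk <- pk[sel, , drop = FALSE]
  }
  rownames(pk) <- NULL
  pk
}

#' Spectrum value at (or near) a mode frequency
#'
#' The maximum of the spectrum within a halfwidth of a nominal mode
#' frequency — the convention used when reporting coherence values "at" the
#' in-phase and out-of-phase mode frequencies.
#'
#' @param spectrum A `spectrum_set`.
#' @param freq Nominal frequency, THz.
#' @param halfwidth Search halfwidth, THz (0 = nearest bin only).
#' @return Numeric value.
#' @export
spectrum_at <- function(spectrum, freq, halfwidth = 0.1) {
  stopifnot(inherits(spectrum, "spectrum_set"))
  sel <- abs(spectrum$freq - freq) <= max(halfwidth,
                                          diff(spectrum$freq[1:2]) / 2)
  max(spectrum$value[sel], na.rm = TRUE)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set [%s] %s: %d bins, %.4g..%.4g THz\n",
              x$kind, x$label, length(x$freq), min(x$freq), max(x$freq)))
  if (!is.null(x$sd)) cat("  replicate mean +/- SD available\n")
  if (length(x$estimator))
    cat(sprintf("  Welch: %d segments of %d samples\n",
                x$estimator$n_segments, x$estimator$segment_length))
  invisible(x)
}

#' @export
plot.spectrum_set <- function(x, xlim = NULL, ...) {
  y <- x$value
  plot(x$freq, y, type = "l", col = "grey60", xlab = "f [THz]",
       ylab = x$kind, main = x$label, xlim = xlim, ...)
  if (!is.null(x$smooth)) graphics::lines(x$freq, x$smooth, lwd = 2)
  if (!is.null(x$sd)) {
    graphics::lines(x$freq, x$value + x$sd, lty = 3)
    graphics::lines(x$freq, x$value - x$sd, lty = 3)
  }
  invisible(x)
}
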