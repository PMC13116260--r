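# Potentials of mean force by Boltzmann inversion of sampled densities:
# U = -kB T log P, minimum-shifted to zero, with empty bins masked rather
# than extrapolated.

new_pmf_grid <- function(mids, energy, counts, temperature, source = "samples",
                         mids2 = NULL) {
  dim <- if (is.null(mids2)) 1L else 2L
  mask <- if (dim == 1L) is.finite(energy) else is.finite(energy)
  structure(list(dim = dim, mids = mids, mids2 = mids2, energy = energy,
                 counts = counts, mask = mask, temperature = temperature,
                 source = source),
            class = "pmf_grid")
}

#' 1D potential of mean force from axial samples
#'
#' Boltzmann inversion `U(z) = -kB T log(P(z))` of the normalized position
#' histogram, shifted so the minimum over occupied bins is zero. Empty bins
#' are masked (`NA` energy), never extrapolated. Under driving fields the
#' result is a time-averaged steady-state density inversion, not an
#' equilibrium free energy.
#'
#' @param z Axial position samples in angstrom (pool both ions' samples for
#'   a profile spanning both binding sites), or a `ca_trajectory` whose
#'   stored positions are pooled.
#' @param bins Bin width in angstrom, or a vector of break points.
#' @param temperature Temperature in K used in the inversion.
#' @param range Optional c(min, max) clipping range, angstrom.
#' @return A `pmf_grid` with bin centers `mids` (A), `energy` (eV, min 0)
#'   and bin `counts`. The energy in thermal units is `energy / (kBT/e)`;
#'   see [barrier_height()].
#' @export
pmf_1d <- function(z, bins = 0.1, temperature = 310, range = NULL) {
  if (inherits(z, "ca_trajectory")) {
    temperature <- z$config$temperature
    z <- as.numeric(z$z)
  }
  z <- z[is.finite(z)]
  if (!length(z)) stop("no samples: empty histogram")
  if (length(z) < 1e4)
    warning("fewer than 10^4 samples; the PMF will be noisy")
  if (!is.null(range)) z <- z[z >= range[1] & z <= range[2]]
  breaks <- if (length(bins) > 1) bins else {
    lo <- floor(min(z) / bins) * bins
    seq(lo, max(z) + bins, by = bins)
  }
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  kT_eV <- kBT(temperature) / .const$eV
  u <- -kT_eV * log(p)
  u[h$counts == 0] <- NA_real_
  u <- u - min(u, na.rm = TRUE)
  new_pmf_grid(h$mids, u, h$counts, temperature)
}

#' 2D potential of mean force over joint axial displacements
#'
#' Boltzmann inversion of the joint histogram of the two ions' axial
#' displacements from their mean positions. For the calibrated equilibrium
#' pair the well is elliptical and elongated along the main diagonal
#' (in-phase motion is the soft direction).
#'
#' @param dz1,dz2 Displacement samples in angstrom (deviations from each
#'   ion's trajectory mean), or a 2-ion `ca_trajectory` as `dz1`.
#' @param bins Bin width in angstrom.
#' @param temperature Temperature, K.
#' @param limits Half-range of the grid, angstrom (grid spans +/- limits).
#' @return A `pmf_grid` with `dim = 2`: `mids`/`mids2` bin centers, `energy`
#'   and `counts` matrices (rows: dz1, cols: dz2).
#' @export
pmf_2d <- function(dz1, dz2 = NULL, bins = 0.02, temperature = 310,
                   limits = 1.0) {
  if (inherits(dz1, "ca_trajectory")) {
    stopifnot(ncol(dz1$z) == 2)
    temperature <- dz1$config$temperature
    dz2 <- dz1$z[, 2] - mean(dz1$z[, 2])
    dz1 <- dz1$z[, 1] - mean(dz1$z[, 1])
  }
  stopifnot(length(dz1) == length(dz2))
  if (!length(dz1)) stop("no samples: empty histogram")
  if (length(dz1) < 1e4)
    warning("fewer than 10^4 samples; the PMF will be noisy")
  breaks <- seq(-limits, limits, by = bins)
  nb <- length(breaks) - 1
  i <- findInterval(dz1, breaks, rightmost.closed = TRUE)
  j <- findInterval(dz2, breaks, rightmost.closed = TRUE)
  ok <- i >= 1 & i <= nb & j >= 1 & j <= nb
  counts <- matrix(tabulate((j[ok] - 1) * nb + i[ok], nbins = nb * nb), nb, nb)
  p <- counts / sum(counts)
  kT_eV <- kBT(temperature) / .const$eV
  u <- -kT_eV * log(p)
  u[counts == 0] <- NA_real_
  u <- u - min(u, na.rm = TRUE)
  mids <- breaks[-1] - bins / 2
  new_pmf_grid(mids, u, counts, temperature, mids2 = mids)
}

#' Inter-well barrier height of a 1D PMF
#'
#' Maximum energy on the grid path between two well minima, measured from
#' the higher of the two minima; reported in eV with the value in thermal
#' units (`kB T`) as an attribute. If the path crosses empty (masked) bins
#' the barrier cannot be fully resolved from the sampled density: the
#' maximum over the occupied bins is returned as a censored lower bound
#' (attribute `censored = TRUE`, with a warning).
#'
#' @param pmf A 1D `pmf_grid`.
#' @param well_a,well_b Approximate well positions, angstrom; the nearest
#'   occupied local minima are used.
#' @param temperature Temperature for the kBT conversion (defaults to the
#'   grid's).
#' @return Barrier in eV with attributes `kBT`, `censored`, `at` (position of
#'   the maximum, A). Returns 0 with a warning if the wells are not separated
#'   by a maximum.
#' @export
barrier_height <- function(pmf, well_a, well_b, temperature = pmf$temperature) {
  stopifnot(inherits(pmf, "pmf_grid"), pmf$dim == 1L)
  z <- pmf$mids
  u <- pmf$energy
  ia <- which.min(abs(z - well_a))
  ib <- which.min(abs(z - well_b))
  if (ia > ib) { tmp <- ia; ia <- ib; ib <- tmp }
  seg <- seq(ia, ib)
  useg <- u[seg]
  base <- max(u[ia], u[ib], na.rm = TRUE)
  censored <- anyNA(useg)
  if (all(is.na(useg))) stop("no occupied bins between the wells")
  bar <- max(useg, na.rm = TRUE) - base
  if (censored)
    warning("empty bins between the wells: barrier is a censored lower bound")
  if (bar <= 0 && !censored) {
    warning("wells are not separated by a maximum; returning 0")
    bar <- 0
  }
  kT_eV <- kBT(temperature) / .const$eV
  structure(max(bar, 0), kBT = max(bar, 0) / kT_eV, censored = censored,
            at = z[seg][which.max(useg)])
}

#' Locate potential wells of a PMF
#'
#' Local minima of a 1D grid (below an energy ceiling, with a minimum
#' prominence against sampling noise), sorted by position.
#'
#' @param pmf A 1D `pmf_grid`.
#' @param max_energy Only minima at energies below this are reported (eV).
#' @param prominence Required rise on both sides of a minimum (eV).
#' @return `data.frame(position, energy)`.
#' @export
well_minima <- function(pmf, max_energy = Inf, prominence = 0.02) {
  stopifnot(inherits(pmf, "pmf_grid"), pmf$dim == 1L)
  y <- -pmf$energy
  y[!is.finite(y)] <- -Inf
  pk <- find_peaks(structure(list(freq = pmf$mids, value = y, smooth = NULL),
                             class = "spectrum_set"),
                   prominence = prominence)
  pk <- pk[-pk$height <= max_energy, , drop = FALSE]
  out <- data.frame(position = pk$frequency, energy = -pk$height)
  out[order(out$position), , drop = FALSE]
}

#' @export
print.pmf_grid <- function(x, ...) {
  if (x$dim == 1L) {
    cat(sprintf("1D PMF (%s): %d bins over %.4g..%.4g A, T = %g K\n",
                x$source, length(x$mids), min(x$mids), max(x$mids),
                x$temperature))
    cat(sprintf("  occupied bins: %d; max resolved energy %.3g eV\n",
                sum(x$mask), max(x$energy[x$mask])))
  } else {
    cat(sprintf("2D PMF (%s): %d x %d bins over +/-%.3g A, T = %g K\n",
                x$source, length(x$mids), length(x$mids2), max(x$mids),
                x$temperature))
    cat(sprintf("  occupied bins: %d of %d\n", sum(x$mask), length(x$energy)))
  }
  invisible(x)
}

#' @export
plot.pmf_grid <- function(x, in_kBT = FALSE, ...) {
  kT_eV <- kBT(x$temperature) / .const$eV
  if (x$dim == 1L) {
    u <- if (in_kBT) x$energy / kT_eV else x$energy
    plot(x$mids, u, type = "l", xlab = "z [Å]",
         ylab = if (in_kBT) "U [kBT]" else "U [eV]",
         main = "Potential of mean force", ...)
  } else {
    u <- x$energy
    u[!is.finite(u)] <- NA
    graphics::image(x$mids, x$mids2, u, xlab = expression(Delta * z[1]),
                    ylab = expression(Delta * z[2]),
                    main = "2D potential of mean force", ...)
    graphics::contour(x$mids, x$mids2, u, add = TRUE, nlevels = 8)
  }
  invisible(x)
}

#' Export a PMF grid as CSV
#'
#' 1D: columns `z_A`, `U_eV`, `U_kBT`, `count`. 2D long format: `dz1_A`,
#' `dz2_A`, `U_eV`, `count`.
#'
#' @param pmf A `pmf_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_grid"))
  kT_eV <- kBT(pmf$temperature) / .const$eV
  df <- if (pmf$dim == 1L) {
    data.frame(z_A = pmf$mids, U_eV = pmf$energy, U_kBT = pmf$energy / kT_eV,
               count = pmf$counts)
  } else {
    data.frame(dz1_A = rep(pmf$mids, times = length(pmf$mids2)),
               dz2_A = rep(pmf$mids2, each = length(pmf$mids)),
               U_eV = as.numeric(pmf$energy),
               count = as.numeric(pmf$counts))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
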