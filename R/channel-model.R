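#' Construct the equivalent CavAb channel model
#'
#' Builds the static conservative force field for axial Ca2+ dynamics in the
#' CavAb selectivity filter (SF): the Coulomb field of two EEEE-locus rings
#' (four glutamate charges each) and four mouth dipoles, a dielectric
#' self-energy (polarization) barrier across the narrow filter, steep
#' confining walls at the simulation domain ends, an optional linear
#' transmembrane-voltage ramp, and a screened ion-ion Coulomb interaction.
#'
#' The z axis is the permeation axis, increasing toward the extracellular
#' side. The SF spans 10-20 A with binding-site rings at z = 14 A (S1) and
#' z = 18 A (S2); a shallow dipole-generated well sits near z = -17 A, and
#' permeation is counted at the exit plane z = -25 A.
#'
#' Default numeric parameters are the package's calibrated set (see
#' [calibrate_channel()] and the methods vignette): they reproduce a two-ion
#' equilibrium with collective in-phase/out-of-phase modes near 1.65 and
#' 2.84 THz and a static inter-site barrier near 0.63 eV.
#'
#' @param ring_radius Radial distance of the EEEE ring charges from the pore
#'   axis, in angstrom.
#' @param eps_channel Relative permittivity screening ion to fixed-charge
#'   interactions (dimensionless, >= 1).
#' @param eps_ion_ion Relative permittivity prefactor of the ion-ion Coulomb
#'   term (dimensionless, >= 1).
#' @param screening_length Exponential screening length of the ion-ion
#'   interaction, in angstrom (`Inf` gives the bare Coulomb form).
#' @param fixed_screening Exponential screening length of the ion to
#'   fixed-charge Coulomb interactions, in angstrom (`Inf` = bare Coulomb).
#'   Models the reaction-field screening by pore water and the bulk
#'   reservoirs, which confines the influence of the EEEE rings to the pore
#'   neighborhood.
#' @param pol_amplitude,pol_center,pol_width Gaussian dielectric self-energy
#'   barrier: amplitude (eV), axial center (A) and width (A). The bump is
#'   largest in the narrow filter and vanishes in the reservoirs.
#' @param wall_amplitude,wall_width Inverse-power (order 10) confining wall at
#'   the domain ends: energy scale (eV) and onset width (A).
#' @param gamma_rate Axial damping rate gamma/m in 1/s (the Langevin friction
#'   divided by the ion mass). The friction coefficient itself is
#'   `gamma_rate * mass` kg/s.
#' @param temperature Default simulation temperature, K.
#' @param ion_mass Ion mass in kg (default: Ca-40 2+).
#' @param ion_charge Ion charge in C (default +2e).
#' @param geometry Optional named list overriding geometry entries
#'   (`sf_zmin`, `sf_zmax`, `site1_z`, `site2_z`, `dipole_z`, `dipole_radius`,
#'   `dipole_length`, `exit_z`, `res_left`, `res_right`, `domain`,
#'   `membrane`).
#' @param config Optional path to a YAML file with any of the above
#'   parameters (explicit arguments win over the file).
#'
#' @return An object of class `channel_model`.
#' @seealso [axial_potential()], [axial_force()], [simulate.channel_model()],
#'   [calibrate_channel()]
#' @examples
#' ch <- channel_model()
#' axial_potential(ch, c(14, 16, 18))
#' @export
channel_model <- function(ring_radius = NULL,
                          eps_channel = NULL,
                          eps_ion_ion = NULL,
                          screening_length = NULL,
                          fixed_screening = NULL,
                          pol_amplitude = NULL,
                          pol_center = NULL,
                          pol_width = NULL,
                          wall_amplitude = 2.0,
                          wall_width = 1.5,
                          gamma_rate = 1e12,
                          temperature = 310,
                          ion_mass = .ca_mass,
                          ion_charge = .ca_charge,
                          geometry = list(),
                          config = NULL) {
  cfg <- .default_channel_config()
  if (!is.null(config)) {
    user <- yaml::read_yaml(config)
    cfg[names(user)] <- user
  }
  override <- list(ring_radius = ring_radius, eps_channel = eps_channel,
                   eps_ion_ion = eps_ion_ion,
                   screening_length = screening_length,
                   fixed_screening = fixed_screening,
                   pol_amplitude = pol_amplitude, pol_center = pol_center,
                   pol_width = pol_width)
  for (nm in names(override))
    if (!is.null(override[[nm]])) cfg[[nm]] <- override[[nm]]

  geo <- list(
    sf_zmin = 10, sf_zmax = 20, site1_z = 14, site2_z = 18,
    dipole_z = -17, dipole_radius = 5.0, dipole_length = 0.5,
    exit_z = -25, res_left = c(-40, -25), res_right = c(25, 40),
    domain = c(-40, 40), membrane = c(-40, 25)
  )
  geo[names(geometry)] <- geometry
  stopifnot(geo$sf_zmin < geo$site1_z, geo$site1_z < geo$site2_z,
            geo$site2_z < geo$sf_zmax, geo$exit_z < geo$sf_zmin,
            cfg$ring_radius > 0, cfg$eps_channel >= 1, cfg$eps_ion_ion >= 1,
            cfg$pol_amplitude >= 0, gamma_rate > 0, ion_mass > 0,
            ion_charge > 0)

  model <- structure(list(
    geometry = geo,
    dielectric = list(eps_channel = cfg$eps_channel,
                      eps_ion_ion = cfg$eps_ion_ion,
                      screening_length = cfg$screening_length,
                      fixed_screening = cfg$fixed_screening),
    ring = list(radius = cfg$ring_radius, charge = -1.3e-19, n = 4L,
                z = c(geo$site1_z, geo$site2_z)),
    dipole = list(charge = 0.6e-19, n = 4L),
    pol = list(amplitude = cfg$pol_amplitude, center = cfg$pol_center,
               width = cfg$pol_width),
    wall = list(amplitude = wall_amplitude, width = wall_width),
    ion = list(mass = ion_mass, charge = ion_charge,
               gamma = gamma_rate * ion_mass, gamma_rate = gamma_rate),
    temperature = temperature,
    clamp = 0.5
  ), class = "channel_model")
  model$charges <- .fixed_charges(model)
  model
}

# Calibrated defaults shipped with the package (see calibrate_channel()).
.default_channel_config <- function() {
  path <- system.file("extdata", "cavab_calibrated.yaml", package = "cavthz")
  if (nzchar(path)) return(yaml::read_yaml(path))
  # fallback used only before installation
  list(ring_radius = 3.0, eps_channel = 8.0, eps_ion_ion = 2.0,
       screening_length = 0.7, fixed_screening = 8.0, pol_amplitude = 1.0,
       pol_center = 16.0, pol_width = 1.2)
}

# Explicit fixed charges: two EEEE rings of 4 equal charges, and 4 radially
# oriented mouth dipoles (inner negative, outer positive partial charge).
.fixed_charges <- function(model) {
  geo <- model$geometry
  az <- (c(45, 135, 225, 315)) * pi / 180
  ring <- do.call(rbind, lapply(seq_along(model$ring$z), function(i) {
    data.frame(x = model$ring$radius * cos(az),
               y = model$ring$radius * sin(az),
               z = model$ring$z[i],
               q = model$ring$charge,
               label = sprintf("EEEE ring %d charge %d", i, seq_len(4)))
  }))
  rd <- geo$dipole_radius
  dip <- rbind(
    data.frame(x = rd * cos(az), y = rd * sin(az), z = geo$dipole_z,
               q = -model$dipole$charge,
               label = sprintf("dipole %d (-)", seq_len(4))),
    data.frame(x = (rd + geo$dipole_length) * cos(az),
               y = (rd + geo$dipole_length) * sin(az), z = geo$dipole_z,
               q = +model$dipole$charge,
               label = sprintf("dipole %d (+)", seq_len(4)))
  )
  rbind(ring, dip)
}

#' Coulomb energy of a test charge in the fixed-charge field
#'
#' Direct pairwise Coulomb sum over the channel's fixed charges, screened by
#' `eps_channel`, with a minimum-distance clamp (0.5 A) guarding the 1/r
#' singularity.
#'
#' @param model A [channel_model()].
#' @param point Numeric length-3 position (x, y, z) in angstrom.
#' @param q_test Test charge in coulomb (default: the model ion's charge).
#' @return Energy in eV.
#' @export
coulomb_energy <- function(model, point, q_test = model$ion$charge) {
  stopifnot(inherits(model, "channel_model"), length(point) == 3)
  ch <- model$charges
  r <- sqrt((ch$x - point[1])^2 + (ch$y - point[2])^2 + (ch$z - point[3])^2)
  if (any(r < 1e-6))
    stop("evaluation point coincides with fixed charge: ",
         ch$label[which.min(r)])
  if (any(r < model$clamp)) {
    message("coulomb_energy: ", sum(r < model$clamp),
            " distance(s) clamped to ", model$clamp, " A")
    r <- pmax(r, model$clamp)
  }
  lam <- model$dielectric$fixed_screening
  sum(.const$ke * q_test * ch$q * exp(-r / lam) /
        (model$dielectric$eps_channel * r * .const$ang)) / .const$eV
}

# --- axial (on-axis) potential components, vectorized over z [A] -> eV ------

.u_ring_axial <- function(model, z) {
  eps <- model$dielectric$eps_channel
  lam <- model$dielectric$fixed_screening
  qq <- model$ion$charge * model$ring$charge * model$ring$n
  out <- 0
  for (zr in model$ring$z) {
    r <- sqrt((z - zr)^2 + model$ring$radius^2)
    out <- out + .const$ke * qq * exp(-r / lam) / (eps * r * .const$ang)
  }
  out / .const$eV
}

.u_dipole_axial <- function(model, z) {
  geo <- model$geometry
  eps <- model$dielectric$eps_channel
  lam <- model$dielectric$fixed_screening
  q <- model$ion$charge * model$dipole$charge * model$dipole$n
  rn <- sqrt((z - geo$dipole_z)^2 + geo$dipole_radius^2)
  rp <- sqrt((z - geo$dipole_z)^2 +
               (geo$dipole_radius + geo$dipole_length)^2)
  .const$ke * q * (-exp(-rn / lam) / rn + exp(-rp / lam) / rp) /
    (eps * .const$ang) / .const$eV
}

.u_pol <- function(model, z) {
  p <- model$pol
  p$amplitude * exp(-(z - p$center)^2 / (2 * p$width^2))
}

.u_wall <- function(model, z) {
  w <- model$wall
  d <- model$geometry$domain
  lo <- pmax(0, (d[1] + w$width - z) / w$width)
  hi <- pmax(0, (z - (d[2] - w$width)) / w$width)
  w$amplitude * (lo^10 + hi^10)
}

.u_voltage <- function(model, z, voltage) {
  if (voltage == 0) return(0 * z)
  m <- model$geometry$membrane
  phi <- pmin(1, pmax(0, (m[2] - z) / (m[2] - m[1])))
  (model$ion$charge / .const$e) * voltage * phi
}

.u_pair <- function(model, dz) {
  r <- pmax(abs(dz), model$clamp)
  d <- model$dielectric
  .const$ke * model$ion$charge^2 * exp(-r / d$screening_length) /
    (d$eps_ion_ion * r * .const$ang) / .const$eV
}

#' Total axial potential energy of one ion
#'
#' Sum of the on-axis ring and dipole Coulomb terms, the dielectric
#' self-energy barrier, the confining wall, the transmembrane-voltage ramp,
#' and the screened Coulomb repulsion from any other ions on the axis.
#' With no other ions and the calibrated defaults the profile has two deep
#' wells near z = 14 and 18 A and a shallow well near z = -17 A.
#'
#' @inheritParams coulomb_energy
#' @param z Axial positions in angstrom (vectorized).
#' @param other_ion_z Axial positions (A) of other ions contributing screened
#'   Coulomb repulsion.
#' @param voltage Transmembrane voltage in volt (e.g. -0.4); applied as a
#'   linear ramp across the membrane span.
#' @return Energy in eV, same length as `z`.
#' @export
axial_potential <- function(model, z, other_ion_z = numeric(), voltage = 0) {
  stopifnot(inherits(model, "channel_model"), is.numeric(z))
  u <- .u_ring_axial(model, z) + .u_dipole_axial(model, z) +
    .u_pol(model, z) + .u_wall(model, z) + .u_voltage(model, z, voltage)
  for (zo in other_ion_z) u <- u + .u_pair(model, z - zo)
  u
}

# --- analytic axial derivatives dU/dz [eV/A] --------------------------------

.du_ring_axial <- function(model, z) {
  eps <- model$dielectric$eps_channel
  lam <- model$dielectric$fixed_screening
  qq <- model$ion$charge * model$ring$charge * model$ring$n
  out <- 0
  for (zr in model$ring$z) {
    r <- sqrt((z - zr)^2 + model$ring$radius^2)
    # d/dz [exp(-r/lam)/r] = -exp(-r/lam) (1/r + 1/lam) (z-zr) / r^2
    out <- out - .const$ke * qq * exp(-r / lam) * (1 / r + 1 / lam) *
      (z - zr) / (eps * r^2 * .const$ang)
  }
  out / .const$eV
}

.du_dipole_axial <- function(model, z) {
  geo <- model$geometry
  eps <- model$dielectric$eps_channel
  lam <- model$dielectric$fixed_screening
  q <- model$ion$charge * model$dipole$charge * model$dipole$n
  dz <- z - geo$dipole_z
  rn <- sqrt(dz^2 + geo$dipole_radius^2)
  rp <- sqrt(dz^2 + (geo$dipole_radius + geo$dipole_length)^2)
  .const$ke * q * dz *
    (exp(-rn / lam) * (1 / rn + 1 / lam) / rn^2 -
     exp(-rp / lam) * (1 / rp + 1 / lam) / rp^2) /
    (eps * .const$ang) / .const$eV
}

.du_pol <- function(model, z) {
  p <- model$pol
  -.u_pol(model, z) * (z - p$center) / p$width^2
}

.du_wall <- function(model, z) {
  w <- model$wall
  d <- model$geometry$domain
  lo <- pmax(0, (d[1] + w$width - z) / w$width)
  hi <- pmax(0, (z - (d[2] - w$width)) / w$width)
  w$amplitude * 10 * (hi^9 - lo^9) / w$width
}

.du_voltage <- function(model, z, voltage) {
  if (voltage == 0) return(0 * z)
  m <- model$geometry$membrane
  inside <- z > m[1] & z < m[2]
  -(model$ion$charge / .const$e) * voltage * inside / (m[2] - m[1])
}

# signed derivative of the pair term w.r.t. the first ion's z
.du_pair <- function(model, dz) {
  d <- model$dielectric
  r <- pmax(abs(dz), model$clamp)
  u <- .const$ke * model$ion$charge^2 * exp(-r / d$screening_length) /
    (d$eps_ion_ion * r * .const$ang) / .const$eV
  -sign(dz) * u * (1 / r + 1 / d$screening_length)
}

#' Axial forces on a set of ions
#'
#' Negative analytic gradient of the total axial potential with respect to
#' each ion's position, plus the time-dependent field force `q E_z(t)` when a
#' [field_protocol()] is supplied. Ion-ion contributions are equal and
#' opposite by construction.
#'
#' @inheritParams axial_potential
#' @param z Positions of all ions, angstrom.
#' @param t Time in seconds (used for the driving field).
#' @param protocol A [field_protocol()] or `NULL`.
#' @return Force in newton per ion.
#' @export
axial_force <- function(model, z, t = 0, protocol = NULL, voltage = 0) {
  stopifnot(inherits(model, "channel_model"))
  du <- .du_ring_axial(model, z) + .du_dipole_axial(model, z) +
    .du_pol(model, z) + .du_wall(model, z) + .du_voltage(model, z, voltage)
  n <- length(z)
  if (n > 1) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) du[i] <- du[i] + .du_pair(model, z[i] - z[j])
      }
    }
  }
  f <- -du * .const$eV / .const$ang          # eV/A -> N
  if (!is.null(protocol))
    f <- f + model$ion$charge * thz_field(protocol, t)
  if (any(!is.finite(f)))
    stop("non-finite force at z = ",
         paste(signif(z[!is.finite(f)], 6), collapse = ", "), " A")
  f
}

#' Potential energy map on the longitudinal cross-section
#'
#' Energy of a test ion on the XOZ plane: explicit fixed-charge Coulomb sum
#' plus the axial self-energy, wall and voltage terms. Mirror-symmetric in x
#' for the symmetric ring geometry; the on-axis slice (x = 0) equals
#' [axial_potential()].
#'
#' @inheritParams axial_potential
#' @param x,z Grid coordinates in angstrom.
#' @return Object of class `channel_map`: list with `x`, `z` and the energy
#'   matrix `U` (eV, `length(x)` by `length(z)`).
#' @export
potential_map_2d <- function(model, x, z, voltage = 0) {
  stopifnot(inherits(model, "channel_model"))
  ch <- model$charges
  eps <- model$dielectric$eps_channel
  U <- matrix(0, length(x), length(z))
  lam <- model$dielectric$fixed_screening
  for (k in seq_len(nrow(ch))) {
    dx2 <- (x - ch$x[k])^2 + ch$y[k]^2
    r <- sqrt(outer(dx2, (z - ch$z[k])^2, `+`))
    r <- pmax(r, model$clamp)
    U <- U + .const$ke * model$ion$charge * ch$q[k] * exp(-r / lam) /
      (eps * r * .const$ang)
  }
  U <- U / .const$eV
  uz <- .u_pol(model, z) + .u_wall(model, z) + .u_voltage(model, z, voltage)
  U <- sweep(U, 2, uz, `+`)
  structure(list(x = x, z = z, U = U), class = "channel_map")
}

#' Effective harmonic frequency of a potential well
#'
#' Quadratic fit of the well bottom over a window and conversion to an
#' oscillation frequency `f = sqrt(k/m)/(2 pi)`. This is the calibration aid
#' used to match the collective-mode frequencies of the confined ion pair.
#'
#' @param object A [channel_model()] or a function `z -> energy (eV)`.
#' @param site_z Center of the fit window, angstrom.
#' @param window Full window width, angstrom.
#' @param mass Oscillator mass in kg (defaults to the model ion's mass).
#' @param other_ion_z,voltage Passed to [axial_potential()] when `object` is
#'   a model.
#' @param n Number of fit points.
#' @return Frequency in THz, with attributes `k` (N/m) and `z_min` (A).
#' @export
fit_harmonic_curvature <- function(object, site_z, window = 0.5,
                                   mass = .ca_mass, other_ion_z = numeric(),
                                   voltage = 0, n = 41) {
  zg <- seq(site_z - window / 2, site_z + window / 2, length.out = n)
  u <- if (inherits(object, "channel_model")) {
    mass <- object$ion$mass
    axial_potential(object, zg, other_ion_z = other_ion_z, voltage = voltage)
  } else if (is.function(object)) {
    object(zg)
  } else stop("object must be a channel_model or a potential function")
  fit <- stats::lm(u ~ zg + I(zg^2))
  c2 <- unname(stats::coef(fit)[3])
  if (!is.finite(c2) || c2 <= 0)
    stop("no potential minimum in window around z = ", site_z,
         " A (quadratic coefficient ", signif(c2, 3), ")")
  zmin <- -unname(stats::coef(fit)[2]) / (2 * c2)
  if (zmin < min(zg) || zmin > max(zg))
    stop("fitted minimum (", signif(zmin, 4),
         " A) lies outside the window around z = ", site_z, " A")
  k <- 2 * c2 * .const$eV / .const$ang^2    # eV/A^2 -> N/m
  f <- sqrt(k / mass) / (2 * pi) / .const$THz
  structure(f, k = k, z_min = zmin)
}

#' Static equilibrium of the confined ion pair
#'
#' Minimizes the total two-ion energy (channel potential of each ion plus the
#' screened ion-ion repulsion) starting from the binding-site positions.
#' Coulomb repulsion displaces the ions from the single-ion minima.
#'
#' @inheritParams axial_potential
#' @param start Starting positions, angstrom.
#' @return Numeric length-2 equilibrium positions (A), with attribute
#'   `energy` (eV).
#' @export
two_ion_equilibrium <- function(model,
                                start = c(model$geometry$site1_z,
                                          model$geometry$site2_z),
                                voltage = 0) {
  fn <- function(p) {
    axial_potential(model, p[1], voltage = voltage) +
      axial_potential(model, p[2], voltage = voltage) +
      .u_pair(model, p[1] - p[2])
  }
  gr <- function(p) {
    -axial_force(model, p, voltage = voltage) * .const$ang / .const$eV
  }
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  structure(sort(opt$par), energy = opt$value)
}

#' Collective normal modes of the confined ion pair
#'
#' Numerical Hessian of the total two-ion energy at the static equilibrium,
#' diagonalized to give the in-phase and out-of-phase collective mode
#' frequencies of the bound pair.
#'
#' @inheritParams two_ion_equilibrium
#' @param eq Optional equilibrium positions (A); computed if missing.
#' @param h Finite-difference step, angstrom.
#' @return List with `freq_THz` (ascending), `vectors` (columns, in position
#'   space), `labels` (`"in-phase"`/`"out-of-phase"`), `positions` (A) and the
#'   Hessian `K` in N/m.
#' @export
normal_modes <- function(model, eq = NULL, voltage = 0, h = 0.005) {
  if (is.null(eq)) eq <- two_ion_equilibrium(model, voltage = voltage)
  fn <- function(p) {
    axial_potential(model, p[1], voltage = voltage) +
      axial_potential(model, p[2], voltage = voltage) +
      .u_pair(model, p[1] - p[2])
  }
  K <- matrix(0, 2, 2)
  f0 <- fn(eq)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
      K[i, j] <- (fn(eq + ei + ej) - fn(eq + ei - ej) -
                  fn(eq - ei + ej) + fn(eq - ei - ej)) / (4 * h^2)
    }
  }
  K <- (K + t(K)) / 2 * .const$eV / .const$ang^2   # N/m
  es <- eigen(K, symmetric = TRUE)
  ord <- order(es$values)
  lam <- es$values[ord]
  vec <- es$vectors[, ord, drop = FALSE]
  if (any(lam <= 0))
    warning("equilibrium is not a stable minimum (non-positive curvature)")
  freq <- sqrt(pmax(lam, 0) / model$ion$mass) / (2 * pi) / .const$THz
  labels <- ifelse(apply(vec, 2, function(v) prod(sign(v)) > 0),
                   "in-phase", "out-of-phase")
  list(freq_THz = freq, vectors = vec, labels = labels,
       positions = as.numeric(eq), K = K)
}

#' Static axial potential profile as a PMF grid
#'
#' Evaluates the single-ion axial potential on a grid and wraps it as a
#' `pmf_grid` (see [pmf_1d()]) (minimum shifted to zero) so that [well_minima()] and
#' [barrier_height()] apply to the static landscape as well as to sampled
#' densities.
#'
#' @inheritParams axial_potential
#' @param z Grid of axial positions, angstrom.
#' @return A `pmf_grid` object (source `"static"`).
#' @export
potential_profile <- function(model, z = seq(model$geometry$domain[1] + 2,
                                             model$geometry$domain[2] - 2,
                                             by = 0.05),
                              other_ion_z = numeric(), voltage = 0) {
  u <- axial_potential(model, z, other_ion_z = other_ion_z, voltage = voltage)
  new_pmf_grid(mids = z, energy = u - min(u), counts = rep(NA_real_, length(z)),
               temperature = model$temperature, source = "static")
}

#' @export
print.channel_model <- function(x, ...) {
  d <- x$dielectric
  cat("Equivalent CavAb channel model (axial Langevin force field)\n")
  cat(sprintf("  SF span %g..%g A, sites S1/S2 at z = %g/%g A, exit at %g A\n",
              x$geometry$sf_zmin, x$geometry$sf_zmax, x$geometry$site1_z,
              x$geometry$site2_z, x$geometry$exit_z))
  cat(sprintf("  EEEE rings: 4 x %.2g C at radius %.3g A; dipoles: 4 x %.2g C at z = %g A\n",
              x$ring$charge, x$ring$radius, x$dipole$charge, x$geometry$dipole_z))
  cat(sprintf("  eps_channel = %.3g, eps_ion_ion = %.3g, screening length = %.3g A\n",
              d$eps_channel, d$eps_ion_ion, d$screening_length))
  cat(sprintf("  self-energy bump: %.3g eV at z = %.3g A (width %.3g A)\n",
              x$pol$amplitude, x$pol$center, x$pol$width))
  cat(sprintf("  ion: m = %.4g kg, q = %.4g C, gamma/m = %.3g 1/s; T = %g K\n",
              x$ion$mass, x$ion$charge, x$ion$gamma_rate, x$temperature))
  invisible(x)
}

#' @export
summary.channel_model <- function(object, ...) {
  eq <- two_ion_equilibrium(object)
  nm <- normal_modes(object, eq = eq)
  prof <- potential_profile(object,
                            z = seq(object$geometry$sf_zmin,
                                    object$geometry$sf_zmax, by = 0.02))
  wells <- well_minima(prof)
  bar <- if (nrow(wells) >= 2)
    barrier_height(prof, wells$position[1], wells$position[nrow(wells)],
                   temperature = object$temperature)
  else NA_real_
  out <- list(model = object, equilibrium = as.numeric(eq), modes = nm,
              single_ion_wells = wells, static_barrier_eV = as.numeric(bar))
  class(out) <- "summary.channel_model"
  out
}

#' @export
print.summary.channel_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  two-ion equilibrium: z = %.2f, %.2f A\n",
              x$equilibrium[1], x$equilibrium[2]))
  cat(sprintf("  collective modes: %.3f THz (%s), %.3f THz (%s)\n",
              x$modes$freq_THz[1], x$modes$labels[1],
              x$modes$freq_THz[2], x$modes$labels[2]))
  if (nrow(x$single_ion_wells))
    cat("  single-ion SF wells at z =",
        paste(sprintf("%.2f", x$single_ion_wells$position), collapse = ", "),
        "A\n")
  cat(sprintf("  static inter-site barrier: %.3f eV\n", x$static_barrier_eV))
  invisible(x)
}

#' @export
plot.channel_model <- function(x, what = c("profile", "map"),
                               voltage = 0, ...) {
  what <- match.arg(what)
  if (what == "profile") {
    z <- seq(x$geometry$domain[1] + 2, x$geometry$domain[2] - 2, by = 0.05)
    u <- axial_potential(x, z, voltage = voltage)
    plot(z, u, type = "l", xlab = "z [Å]", ylab = "U [eV]",
         main = "Axial potential profile", ...)
    graphics::abline(v = c(x$geometry$site1_z, x$geometry$site2_z), lty = 3)
  } else {
    xs <- seq(-6, 6, by = 0.1)
    zs <- seq(x$geometry$domain[1] + 2, x$geometry$domain[2] - 2, by = 0.2)
    m <- potential_map_2d(x, xs, zs, voltage = voltage)
    graphics::image(m$x, m$z, pmin(m$U, stats::quantile(m$U, 0.98)),
                    xlab = "x [Å]", ylab = "z [Å]",
                    main = "XOZ potential map", ...)
  }
  invisible(x)
}
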