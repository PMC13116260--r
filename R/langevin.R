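#' THz driving-field protocol
#'
#' A z-directed sinusoidal electric field switched on abruptly at an onset
#' time, as used to drive the confined ion pair at (or off) resonance.
#'
#' @param amplitude Field amplitude in V/nm (e.g. 0.3 for dynamics studies,
#'   3 for permeation runs).
#' @param frequency Drive frequency in THz (1.65 = resonant with the in-phase
#'   mode; 10.0 = non-resonant control).
#' @param onset Onset time in ps (field is zero before; phase is referenced
#'   to the onset).
#' @param phase Phase at onset, radians.
#' @return Object of class `field_protocol`.
#' @export
field_protocol <- function(amplitude = 0.3, frequency = 1.65, onset = 200,
                           phase = 0) {
  stopifnot(amplitude >= 0, !(amplitude > 0 && frequency <= 0))
  structure(list(amplitude = amplitude, frequency = frequency,
                 onset = onset, phase = phase), class = "field_protocol")
}

#' Instantaneous driving field
#'
#' @param protocol A [field_protocol()] (or `NULL` for no field).
#' @param t Time(s) in seconds.
#' @return Field strength in V/m (vectorized over `t`).
#' @export
thz_field <- function(protocol, t) {
  if (is.null(protocol)) return(0 * t)
  stopifnot(inherits(protocol, "field_protocol"), all(t >= -1e-30))
  onset <- protocol$onset * 1e-12
  amp <- protocol$amplitude * 1e9
  f <- protocol$frequency * .const$THz
  ifelse(t < onset, 0,
         amp * sin(2 * pi * f * (t - onset) + protocol$phase))
}

# SI parameter list handed to the C++ force/integrator kernel
.cpp_pars <- function(model, voltage = 0) {
  geo <- model$geometry
  eps <- model$dielectric$eps_channel
  q <- model$ion$charge
  ring_C <- .const$ke * q / eps * c(
    model$ring$n * model$ring$charge,          # EEEE ring 1
    model$ring$n * model$ring$charge,          # EEEE ring 2
    -model$dipole$n * model$dipole$charge,     # dipole inner (-)
    +model$dipole$n * model$dipole$charge      # dipole outer (+)
  )
  ring_zc <- c(model$ring$z, geo$dipole_z, geo$dipole_z) * .const$ang
  ring_R2 <- c(model$ring$radius, model$ring$radius, geo$dipole_radius,
               geo$dipole_radius + geo$dipole_length)^2 * .const$ang^2
  span <- (geo$membrane[2] - geo$membrane[1]) * .const$ang
  list(ring_C = ring_C, ring_zc = ring_zc, ring_R2 = ring_R2,
       ring_ilam = 1 / (model$dielectric$fixed_screening * .const$ang),
       pol_A = model$pol$amplitude * .const$eV,
       pol_zc = model$pol$center * .const$ang,
       pol_w = model$pol$width * .const$ang,
       wall_A = model$wall$amplitude * .const$eV,
       wall_w = model$wall$width * .const$ang,
       wall_lo = (geo$domain[1] + model$wall$width) * .const$ang,
       wall_hi = (geo$domain[2] - model$wall$width) * .const$ang,
       q = q,
       volt_F = if (voltage == 0) 0 else q * voltage / span,
       mem_lo = geo$membrane[1] * .const$ang,
       mem_hi = geo$membrane[2] * .const$ang,
       pair_C = .const$ke * q^2 / model$dielectric$eps_ion_ion,
       pair_lambda = model$dielectric$screening_length * .const$ang,
       clamp = model$clamp * .const$ang)
}

#' Simulate Langevin trajectories of confined ions
#'
#' Integrates the axial Langevin equation for the ions in the channel force
#' field with the BAOAB splitting scheme (half kick, half drift, exact
#' Ornstein-Uhlenbeck velocity refresh, half drift, half kick), with optional
#' THz driving and, for permeation runs, a reset boundary at the channel exit
#' that relocates a permeated ion into the extracellular reservoir.
#'
#' Ions start at the static two-ion equilibrium (a third ion, if present,
#' starts uniformly in the right reservoir) with Maxwell-Boltzmann
#' velocities; an equilibration segment is integrated and discarded before
#' recording begins at `t = 0`.
#'
#' @param object A [channel_model()].
#' @param nsim Number of replicate trajectories; replicate `r` uses seed
#'   `seed + r - 1`.
#' @param seed Integer RNG seed (required for reproducibility contracts).
#' @param duration Recorded duration in seconds (default 400 ps).
#' @param dt Time step in seconds (default 2.5 fs).
#' @param n_ions 2 (bound pair) or 3 (permeation setup).
#' @param voltage Transmembrane voltage, volt.
#' @param protocol Optional [field_protocol()].
#' @param temperature Temperature in K.
#' @param stride Storage stride in steps.
#' @param boundary `"none"` or `"reset"` (reset requires `n_ions >= 3`).
#' @param store If `FALSE`, only permeation events and final state are kept
#'   (for long counting runs).
#' @param equilibration Discarded equilibration time in seconds.
#' @param init Optional initial positions (angstrom).
#' @param ... Unused.
#' @return A `ca_trajectory` (or a list of them when `nsim > 1`) with
#'   elements `time` (s), `z` (A, one column per ion), `v` (m/s), `a`
#'   (m/s^2), `events` (data.frame of reset crossings), `config`, `protocol`
#'   and `seed`.
#' @export
simulate.channel_model <- function(object, nsim = 1, seed = NULL,
                                   duration = 400e-12, dt = 2.5e-15,
                                   n_ions = 2, voltage = 0, protocol = NULL,
                                   temperature = object$temperature,
                                   stride = 1L,
                                   boundary = c("none", "reset"),
                                   store = TRUE,
                                   equilibration = 20e-12,
                                   init = NULL, ...) {
  boundary <- match.arg(boundary)
  stopifnot(dt > 0, duration >= dt, temperature > 0, n_ions >= 1)
  if (boundary == "reset" && n_ions < 3)
    stop("the reset boundary is a permeation setup and requires n_ions >= 3")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (nsim > 1) {
    out <- lapply(seq_len(nsim) - 1L, function(r)
      simulate.channel_model(object, nsim = 1, seed = seed + r,
                             duration = duration, dt = dt, n_ions = n_ions,
                             voltage = voltage, protocol = protocol,
                             temperature = temperature, stride = stride,
                             boundary = boundary, store = store,
                             equilibration = equilibration, init = init))
    class(out) <- "ca_trajectory_list"
    return(out)
  }

  set.seed(seed)
  geo <- object$geometry
  if (is.null(init)) {
    eq <- two_ion_equilibrium(object, voltage = voltage)
    init <- as.numeric(eq)[1:2]
    if (n_ions == 1) init <- geo$site1_z
    if (n_ions >= 3)
      init <- c(init, stats::runif(n_ions - 2, geo$res_right[1],
                                   geo$res_right[2]))
  }
  stopifnot(length(init) == n_ions)
  mass <- object$ion$mass
  vth <- sqrt(.const$kB * temperature / mass)
  v0 <- stats::rnorm(n_ions, 0, vth)
  pars <- .cpp_pars(object, voltage = voltage)

  famp <- if (is.null(protocol)) 0 else protocol$amplitude * 1e9
  ffreq <- if (is.null(protocol)) 1 else protocol$frequency * .const$THz
  fonset <- if (is.null(protocol)) 0 else protocol$onset * 1e-12
  fphase <- if (is.null(protocol)) 0 else protocol$phase

  z0 <- init * .const$ang
  # equilibration: no field, no event recording, state carried over
  if (equilibration > 0) {
    neq <- ceiling(equilibration / dt)
    eqr <- baoab_channel_run(pars, z0, v0, dt, neq, object$ion$gamma, mass,
                             temperature, 0, 1, 0, 0, 1L,
                             FALSE, geo$exit_z * .const$ang,
                             geo$res_right[1] * .const$ang,
                             geo$res_right[2] * .const$ang, FALSE, 0)
    z0 <- eqr$z_final
    v0 <- eqr$v_final
  }
  nsteps <- round(duration / dt)
  res <- baoab_channel_run(pars, z0, v0, dt, nsteps, object$ion$gamma, mass,
                           temperature, famp, ffreq, fonset, fphase,
                           as.integer(stride),
                           boundary == "reset", geo$exit_z * .const$ang,
                           geo$res_right[1] * .const$ang,
                           geo$res_right[2] * .const$ang, store, 0)

  events <- data.frame(time = res$event_times, ion = res$event_ion)
  structure(list(
    time = if (store) res$time else numeric(),
    z = if (store) res$z / .const$ang else NULL,
    v = if (store) res$v else NULL,
    a = if (store) res$a else NULL,
    events = events,
    config = list(dt = dt, duration = duration, temperature = temperature,
                  n_ions = n_ions, voltage = voltage, stride = stride,
                  boundary = boundary, equilibration = equilibration,
                  seed = seed),
    protocol = protocol,
    seed = seed
  ), class = "ca_trajectory")
}

#' Count permeation events of a trajectory
#'
#' Number of logged exit-plane crossings (reset-boundary relocations).
#'
#' @param traj A `ca_trajectory`, or a list of them.
#' @return Integer count (vector for a list).
#' @export
count_permeations <- function(traj) {
  if (inherits(traj, "ca_trajectory_list") ||
      (is.list(traj) && !inherits(traj, "ca_trajectory")))
    return(vapply(traj, count_permeations, integer(1)))
  stopifnot(inherits(traj, "ca_trajectory"))
  nrow(traj$events)
}

#' Center-of-mass axial position of the stored ions
#'
#' @param traj A `ca_trajectory` (with stored positions).
#' @param ions Columns to average (default: all).
#' @return Numeric vector in angstrom.
#' @export
com_position <- function(traj, ions = seq_len(ncol(traj$z))) {
  stopifnot(inherits(traj, "ca_trajectory"), !is.null(traj$z))
  rowMeans(traj$z[, ions, drop = FALSE])
}

#' Reference BAOAB integration in simple analytic potentials
#'
#' Single-particle BAOAB runs in a free, harmonic or symmetric quartic
#' double-well potential, used for integrator-physics validation
#' (equipartition, Maxwell-Boltzmann velocities, free diffusion).
#'
#' @param kind `"free"`, `"harmonic"` or `"double_well"`.
#' @param pars For `"harmonic"`: `c(k)` spring constant N/m. For
#'   `"double_well"`: `c(h, a)` barrier height (J) and minima (+/- a, m).
#' @param z0,v0 Initial position (m) and velocity (m/s).
#' @param dt Time step, s.
#' @param nsteps Number of steps.
#' @param gamma Friction coefficient, kg/s.
#' @param mass Particle mass, kg.
#' @param temperature Temperature, K (0 for deterministic damped dynamics).
#' @param stride Storage stride.
#' @param seed Optional RNG seed.
#' @return List with vectors `z` (m) and `v` (m/s).
#' @export
baoab_reference <- function(kind = c("free", "harmonic", "double_well"),
                            pars = numeric(), z0 = 0, v0 = 0, dt = 2.5e-15,
                            nsteps = 1e5, gamma = .ca_mass * 1e12,
                            mass = .ca_mass, temperature = 310, stride = 1L,
                            seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  baoab_reference_run(match(kind, c("free", "harmonic", "double_well")) - 1L,
                      as.numeric(pars), z0, v0, dt, nsteps, gamma, mass,
                      temperature, as.integer(stride))
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Langevin trajectory: %d ion(s), %.4g ns at dt = %.3g fs (T = %g K)\n",
              cfg$n_ions, cfg$duration * 1e9, cfg$dt * 1e15, cfg$temperature))
  if (!is.null(x$protocol))
    cat(sprintf("  driven: %.3g V/nm at %.3g THz from t = %g ps\n",
                x$protocol$amplitude, x$protocol$frequency, x$protocol$onset))
  if (cfg$voltage != 0)
    cat(sprintf("  transmembrane voltage: %g mV\n", cfg$voltage * 1e3))
  cat(sprintf("  stored samples: %d (stride %d); permeation events: %d; seed %s\n",
              length(x$time), cfg$stride, nrow(x$events), format(x$seed)))
  invisible(x)
}

#' @export
plot.ca_trajectory <- function(x, ions = seq_len(ncol(x$z)), ...) {
  stopifnot(!is.null(x$z))
  tps <- x$time * 1e12
  graphics::matplot(tps, x$z[, ions, drop = FALSE], type = "l", lty = 1,
                    xlab = "t [ps]", ylab = "z [Å]",
                    main = "Axial ion trajectories", ...)
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Long-format table with columns `time_s`, `ion`, `z_A`, `v_ms`, `a_ms2`.
#'
#' @param traj A `ca_trajectory` with stored samples.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ca_trajectory"), !is.null(traj$z))
  n <- ncol(traj$z)
  df <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(time_s = traj$time, ion = i, z_A = traj$z[, i],
               v_ms = traj$v[, i], a_ms2 = traj$a[, i])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
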