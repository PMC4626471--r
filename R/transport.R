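# Trajectory integration through the pulsatile field-and-flow environment,
# wall/capture rules, capture efficiency, and parameter sweeps.

#' Assemble a full simulation configuration
#'
#' Defaults reproduce the study conditions: 6000 particles injected in six
#' pulses over the first 0.05 s of the cardiac cycle into a 4 mm channel at
#' 0.10 m/s mean pulsatile flow, observed for 5 s, with the magnet calibrated
#' to 0.5 T and 180 T/m at the vessel center. Desk-scale runs pass a smaller
#' `n_particles`.
#'
#' @param particle a [particle_spec()].
#' @param geometry a [channel_geometry()].
#' @param waveform a [make_waveform()] object.
#' @param viscosity a [viscosity_params()].
#' @param magnet a [magnet_spec()], or `NULL` to calibrate the default magnet
#'   to `b_target`/`grad_target` at the vessel center under the footprint.
#' @param blood a [blood_magnetics()].
#' @param b_target,grad_target calibration targets (T, T/m) used when
#'   `magnet` is `NULL`.
#' @param n_particles total particles injected.
#' @param injection_times injection pulse times (s), even split.
#' @param dt time step (s).
#' @param t_max observation window (s).
#' @param temperature absolute temperature (K).
#' @param eta_drag dynamic viscosity of blood used for the particle-scale
#'   Stokes drag and Brownian amplitude, kg/(m s). A moving particle probes
#'   blood at its own slip shear rate (of order `v_slip / D`, well into the
#'   Newtonian plateau), so the constant plateau value applies rather than
#'   the bulk low-shear apparent viscosity; the generalized power-law model
#'   shapes the velocity profile only.
#' @param seed master RNG seed (integer); per-particle noise substreams are
#'   derived from it, so trajectories are stable under `n_particles` changes.
#' @param brownian logical, include the Brownian force.
#' @param integrator `"overdamped"` (default; valid since tau_p << dt for
#'   nanoparticles) or `"inertial"` (exponential integrator of the linear
#'   drag ODE; unconditionally stable).
#' @param profile_mode `"mixed"` (plug upstream of the footprint, developed
#'   from the footprint on), `"plug"`, or `"developed"`.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(particle = particle_spec(),
                              geometry = channel_geometry(),
                              waveform = make_waveform(),
                              viscosity = viscosity_params(),
                              magnet = NULL,
                              blood = blood_magnetics(),
                              b_target = 0.5, grad_target = 180,
                              n_particles = 6000,
                              injection_times = seq(0, 0.05, by = 0.01),
                              dt = 1e-4, t_max = 5, temperature = 310,
                              eta_drag = 0.0035,
                              seed = 1, brownian = TRUE,
                              integrator = c("overdamped", "inertial"),
                              profile_mode = c("mixed", "plug", "developed")) {
  integrator <- match.arg(integrator)
  profile_mode <- match.arg(profile_mode)
  stopifnot(n_particles > 0, dt > 0, t_max > 0, temperature > 0,
            all(injection_times >= 0), all(injection_times < t_max))
  if (is.null(magnet)) {
    x_mid <- base::mean(geometry$footprint)
    target <- c(x_mid, geometry$width / 2)
    m0 <- pole_array_spec(b_rem = 1, n_poles = 4, center_x = x_mid,
                          face_y = -1e-4, pole_width = 0.011,
                          pole_height = 0.02, gap = 0.0008)
    magnet <- calibrate_magnet(m0, target, b_target, grad_target,
                               standoff_min = geometry$width / 2 + 1e-4)
  }
  tables <- .profile_tables(geometry, viscosity, waveform)
  structure(list(particle = particle, geometry = geometry,
                 waveform = waveform, viscosity = viscosity,
                 tables = tables,
                 magnet = magnet, blood = blood,
                 n_particles = as.integer(n_particles),
                 injection_times = injection_times, dt = dt, t_max = t_max,
                 temperature = temperature, eta_drag = eta_drag, seed = seed,
                 brownian = isTRUE(brownian), integrator = integrator,
                 profile_mode = profile_mode),
            class = "simulation_config")
}

# which wall faces the magnet (capture-eligible side)
.capture_wall <- function(config) {
  mags <- if (inherits(config$magnet, "magnet_spec")) list(config$magnet)
          else config$magnet
  yc <- base::mean(vapply(mags, function(m) m$center[2], numeric(1)))
  if (yc > config$geometry$width / 2) 1L else -1L
}

.env_list <- function(config, rec_idx = integer(0), rec_every = 1L) {
  tabs <- config$tables
  if (is.null(tabs))
    tabs <- .profile_tables(config$geometry, config$viscosity,
                            config$waveform)
  mags <- if (inherits(config$magnet, "magnet_spec")) list(config$magnet)
          else config$magnet
  p <- config$particle
  list(magnets = do.call(rbind, lapply(mags, .magnet_matrix)),
       chi_b = config$blood$chi_b,
       width = config$geometry$width,
       f0 = config$geometry$footprint[1], f1 = config$geometry$footprint[2],
       length = config$geometry$length,
       capture_wall = .capture_wall(config),
       wave_coef = config$waveform$coef, period = config$waveform$period,
       m_grid = tabs$m_grid, y_grid = tabs$y_grid,
       u_tab = tabs$u_tab,
       profile_mode = switch(config$profile_mode,
                             plug = 0L, developed = 1L, mixed = 2L),
       eta_drag = config$eta_drag,
       r_core = p$core_radius, r_h = p$r_h, D = p$diameter,
       rho_eff = p$rho_eff,
       K_cm = clausius_mossotti(p$chi_core, config$blood$chi_b),
       temperature = config$temperature,
       n = config$n_particles, inj_times = config$injection_times,
       dt = config$dt, t_max = config$t_max, seed = config$seed,
       brownian = as.integer(config$brownian),
       integrator = if (config$integrator == "overdamped") 0L else 1L,
       rec_idx = as.integer(rec_idx), rec_every = as.integer(rec_every))
}

#' Initial particle states
#'
#' Splits the particles evenly across the injection pulses, draws transverse
#' inlet positions uniformly over `(r_h, width - r_h)` from the per-particle
#' seeded substreams, and assigns the local plug inlet velocity.
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per particle: `injection_time, x, y,
#'   vx, vy, status`.
#' @export
inject <- function(config) {
  env <- .env_list(config)
  env$t_max <- config$dt / 2     # run zero steps; only initialization
  env$inj_times <- rep(config$t_max / 2, length(config$injection_times))
  res <- run_sim_cpp(env)
  n <- config$n_particles
  k <- length(config$injection_times)
  gi <- floor((seq_len(n) - 1) * k / n) + 1
  data.frame(injection_time = config$injection_times[gi],
             x = res$x, y = res$y,
             vx = mean_velocity(config$injection_times[gi], config$waveform),
             vy = 0, status = "flowing")
}

#' Advance one particle a single step (reference integrator)
#'
#' Scalar reference implementation of the two integrator contracts used by
#' the compiled loop, for a frozen environment: fluid velocity `u_b`, a
#' constant external force, viscosity `eta`. The overdamped mode moves at
#' `u_b + F / (3 pi eta D)`; the inertial mode integrates the linear drag
#' ODE exactly over the step (exponential integrator), so both are stable
#' for any `dt`.
#'
#' @param position,velocity length-2 state vectors (m, m/s).
#' @param dt time step, s.
#' @param u_b local fluid velocity, length-2 (m/s).
#' @param force constant non-drag force over the step, length-2 (N).
#' @param spec a [particle_spec()].
#' @param eta dynamic viscosity, kg/(m s).
#' @param mode `"overdamped"` or `"inertial"`.
#' @return list with updated `position` and `velocity`.
#' @export
particle_step <- function(position, velocity, dt, u_b, force, spec, eta,
                          mode = c("overdamped", "inertial")) {
  mode <- match.arg(mode)
  if (any(!is.finite(force))) stop("non-finite force")
  drag3 <- 3 * pi * eta * spec$diameter
  ueq <- u_b + force / drag3
  if (mode == "overdamped") {
    list(position = position + ueq * dt, velocity = ueq)
  } else {
    tau <- relaxation_time(spec, eta)
    e <- exp(-dt / tau)
    dv <- velocity - ueq
    list(position = position + ueq * dt + tau * (1 - e) * dv,
         velocity = ueq + dv * e)
  }
}

#' Wall interaction rule
#'
#' A particle whose surface reaches a wall is captured if the contact lies
#' inside the magnet footprint on the wall facing the magnet and the
#' wall-normal component of the magnetophoretic force presses it into that
#' wall; otherwise it reflects specularly and elastically. With the magnet
#' off the capture predicate is unreachable.
#'
#' @param position,velocity length-2 state after a step (m, m/s).
#' @param f_m magnetophoretic force at the contact, length-2 (N).
#' @param geom a [channel_geometry()].
#' @param r_h hydrodynamic radius (m).
#' @param capture_wall `-1` (lower wall, `y = 0`) or `+1` (upper).
#' @return list with `position`, `velocity`, and `status` (`"flowing"` or
#'   `"captured"`).
#' @export
wall_interaction <- function(position, velocity, f_m, geom, r_h,
                             capture_wall = -1L) {
  x <- position[1]; y <- position[2]
  in_fp <- x >= geom$footprint[1] & x <= geom$footprint[2]
  status <- "flowing"
  if (y < r_h) {
    if (capture_wall == -1L && in_fp && f_m[2] < 0) {
      y <- r_h; status <- "captured"
    } else {
      y <- 2 * r_h - y; velocity[2] <- -velocity[2]
    }
  } else if (y > geom$width - r_h) {
    if (capture_wall == 1L && in_fp && f_m[2] > 0) {
      y <- geom$width - r_h; status <- "captured"
    } else {
      y <- 2 * (geom$width - r_h) - y; velocity[2] <- -velocity[2]
    }
  }
  list(position = c(x, y), velocity = velocity, status = status)
}

#' Capture efficiency
#'
#' The fraction of particles entering the vessel section that do not leave
#' it, `(eps_in - eps_out) / eps_in * 100` (percent).
#'
#' @param eps_in number of particles entering the section (> 0).
#' @param eps_out number leaving it downstream (`0 <= eps_out <= eps_in`).
#' @return efficiency in percent.
#' @export
capture_efficiency <- function(eps_in, eps_out) {
  if (any(eps_in <= 0)) stop("efficiency undefined for eps_in = 0")
  if (any(eps_out < 0 | eps_out > eps_in))
    stop("require 0 <= eps_out <= eps_in")
  (eps_in - eps_out) / eps_in * 100
}

#' Run the capture simulation
#'
#' Integrates all particles until capture, section exit, or `t_max`.
#' `eps_in` counts particles entering the magnet-footprint section; those
#' still in transit inside the section at `t_max` are reported separately
#' and excluded from the efficiency denominator.
#'
#' @param config a [simulation_config()].
#' @param record optional integer vector of particle indices whose
#'   trajectories are recorded.
#' @param record_every record every k-th step (default 10).
#' @return object of class `capture_result`: counts (`eps_in`, `eps_out`,
#'   `n_captured`, `n_flowing`, `n_never_entered`), `efficiency_pct`,
#'   `stderr_pct` (binomial Monte Carlo standard error), particle-level
#'   data.frame `particles`, `re_p_max` / `re_p_violations` (particle
#'   Reynolds number guard), the `seed`, and any recorded `trajectory`.
#' @export
run_simulation <- function(config, record = integer(0), record_every = 10) {
  env <- .env_list(config, rec_idx = record, rec_every = record_every)
  res <- run_sim_cpp(env)
  eps_in <- res$n_entered
  n_cap <- res$n_captured
  n_flow <- res$n_flowing
  eps_out <- eps_in - n_cap - n_flow
  denom <- n_cap + eps_out
  eff <- if (denom > 0) capture_efficiency(denom, eps_out) else NA_real_
  p <- if (denom > 0) n_cap / denom else NA_real_
  status_lab <- c("flowing", "flowing", "captured", "exited",
                  "exited_upstream")[res$status + 1]
  out <- list(
    eps_in = eps_in, eps_out = eps_out, n_captured = n_cap,
    n_flowing = n_flow,
    n_never_entered = config$n_particles - eps_in,
    efficiency_pct = eff,
    stderr_pct = if (denom > 0) 100 * sqrt(p * (1 - p) / denom) else NA_real_,
    re_p_max = res$re_p_max, re_p_violations = res$re_p_violations,
    seed = config$seed,
    particles = data.frame(x = res$x, y = res$y, vx = res$vx, vy = res$vy,
                           status = status_lab,
                           entered = res$entered == 1,
                           capture_time = res$capture_time),
    trajectory = as.data.frame(res$trajectory),
    config = config)
  class(out) <- "capture_result"
  out
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf(
    paste0("capture result (seed %s): eps_in = %d, eps_out = %d, captured = %d,",
           " in transit = %d\n  efficiency = %.2f %% (MC se %.2f %%), max Re_p = %.3g",
           " (%d violations)\n"),
    format(x$seed), x$eps_in, x$eps_out, x$n_captured, x$n_flowing,
    x$efficiency_pct, x$stderr_pct, x$re_p_max, as.integer(x$re_p_violations)))
  invisible(x)
}

#' Capture efficiency as a function of core size
#'
#' Re-runs the simulation for each core radius with a per-radius seed offset
#' and tabulates counts, efficiency, and the binomial Monte Carlo standard
#' error.
#'
#' @param config a [simulation_config()]; its particle's shell is preserved.
#' @param radii core radii (m), each within `[10 nm, 2 um]`.
#' @return data.frame with one row per radius.
#' @export
sweep_core_size <- function(config, radii) {
  if (any(radii < 10e-9 | radii > 2e-6))
    stop("core radii must lie within [10 nm, 2 um]")
  rows <- lapply(seq_along(radii), function(i) {
    cfg <- config
    cfg$particle <- particle_spec(core = config$particle$core,
                                  core_radius = radii[i],
                                  shell = config$particle$shell,
                                  shell_thickness = config$particle$shell_thickness)
    cfg$seed <- config$seed + i
    r <- run_simulation(cfg)
    data.frame(radius_m = radii[i], eps_in = r$eps_in, eps_out = r$eps_out,
               captured = r$n_captured, flowing = r$n_flowing,
               efficiency_pct = r$efficiency_pct, stderr_pct = r$stderr_pct)
  })
  do.call(rbind, rows)
}

#' Capture efficiency across coating materials and thicknesses
#'
#' Fixed magnetic core, varying non-magnetic shell. All cells share the
#' master seed (common random numbers), so a zero-thickness shell reproduces
#' the bare-core run exactly; a bare-core baseline row is always included.
#'
#' @param config a [simulation_config()] providing the core.
#' @param materials coating material names.
#' @param thicknesses shell thicknesses (m), within `[0, 50 nm]` by default
#'   bounds checking.
#' @param max_thickness upper bound for validation (m).
#' @return data.frame over material x thickness plus the bare baseline.
#' @export
sweep_coating <- function(config, materials = c("Au", "SiO2", "PEG"),
                          thicknesses = seq(5e-9, 50e-9, by = 5e-9),
                          max_thickness = 50e-9) {
  if (any(thicknesses < 0 | thicknesses > max_thickness))
    stop("thicknesses must lie within [0, ", max_thickness, "] m")
  grid <- rbind(data.frame(material = "none", thickness_m = 0),
                expand.grid(material = materials, thickness_m = thicknesses,
                            stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    th <- grid$thickness_m[i]
    cfg$particle <- particle_spec(
      core = config$particle$core, core_radius = config$particle$core_radius,
      shell = if (th > 0) grid$material[i] else NULL, shell_thickness = th)
    r <- run_simulation(cfg)
    data.frame(material = grid$material[i], thickness_m = th,
               eps_in = r$eps_in, eps_out = r$eps_out,
               captured = r$n_captured, flowing = r$n_flowing,
               efficiency_pct = r$efficiency_pct, stderr_pct = r$stderr_pct)
  })
  do.call(rbind, rows)
}
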