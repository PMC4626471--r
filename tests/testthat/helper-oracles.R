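# Shared oracles and cached fixtures.

MU0 <- 4e-7 * pi
KB <- 1.380649e-23

# Brute-force Biot-Savart quadrature for the equivalent surface-current
# sheets of a uniformly magnetized rectangle (magnetization along +/- y):
# independent of the closed-form implementation.
biot_savart_field <- function(magnet, point) {
  K <- magnet$b_rem / MU0 * magnet$axis[2]       # sheet current density
  x1 <- magnet$center[1] - magnet$width / 2
  x2 <- magnet$center[1] + magnet$width / 2
  y1 <- magnet$center[2] - magnet$height / 2
  y2 <- magnet$center[2] + magnet$height / 2
  wire <- function(x0, sgn) {
    # field of the sheet at x = x0 carrying sgn * K, integrated over y'
    bx <- integrate(function(yp) {
      r2 <- (point[1] - x0)^2 + (point[2] - yp)^2
      -MU0 * sgn * K / (2 * pi) * (point[2] - yp) / r2
    }, y1, y2, rel.tol = 1e-10)$value
    by <- integrate(function(yp) {
      r2 <- (point[1] - x0)^2 + (point[2] - yp)^2
      MU0 * sgn * K / (2 * pi) * (point[1] - x0) / r2
    }, y1, y2, rel.tol = 1e-10)$value
    c(bx, by)
  }
  wire(x1, 1) + wire(x2, -1)
}

# Direct scalar evaluation of the generalized power-law model, written
# independently of the compiled kernel.
gpl_direct <- function(g, eta_inf = 0.0035, d_eta = 0.025, a = 50, b = 3,
                       n_inf = 1, d_n = 0.45, cc = 50, d = 4) {
  lam <- eta_inf + d_eta * exp(-(1 + g / a) * exp(-b / g))
  n <- n_inf - d_n * exp(-(1 + g / cc) * exp(-d / g))
  lam * g^(n - 1)
}

# One cached base configuration for short transport runs (building the
# velocity-profile tables once keeps the suite fast).
.fixture_env <- new.env(parent = emptyenv())

fast_config <- function() {
  if (is.null(.fixture_env$cfg)) {
    .fixture_env$cfg <- simulation_config(
      particle = particle_spec("Fe3O4", 100e-9),
      n_particles = 60, t_max = 1.2, seed = 101)
  }
  .fixture_env$cfg
}

# full-scale runs shared between the acceptance blocks
acceptance_run <- function(key, radius, n, seed) {
  if (is.null(.fixture_env[[key]])) {
    cfg <- simulation_config(particle = particle_spec("Fe3O4", radius),
                             n_particles = n, seed = seed)
    .fixture_env[[key]] <- run_simulation(cfg)
  }
  .fixture_env[[key]]
}

# pooled binomial standard error (percent) between two sweep rows
pooled_se <- function(e1, se1, e2, se2) sqrt(se1^2 + se2^2)
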