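test_that("injection splits pulses evenly, stays off the walls, and is reproducible", {
  cfg <- fast_config()
  ini <- inject(cfg)
  expect_equal(nrow(ini), cfg$n_particles)
  expect_equal(as.numeric(table(ini$injection_time)),
               rep(cfg$n_particles / 6, 6))
  r_h <- cfg$particle$r_h
  w <- cfg$geometry$width
  expect_true(all(ini$y > r_h & ini$y < w - r_h))
  expect_true(all(ini$x == 0))
  expect_identical(ini, inject(cfg))
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1
  expect_false(isTRUE(all.equal(ini$y, inject(cfg2)$y)))
})

test_that("single-step integrators satisfy their contracts", {
  spec <- particle_spec("Fe3O4", 100e-9)
  eta <- 0.0035
  # equilibrium: no force, particle at fluid velocity -> pure advection
  st <- particle_step(c(0, 0.001), c(0.1, 0), dt = 1e-4, u_b = c(0.1, 0),
                      force = c(0, 0), spec, eta, mode = "inertial")
  expect_equal(st$velocity, c(0.1, 0))
  expect_equal(st$position, c(0.1 * 1e-4, 0.001))
  # inertial mode reaches the terminal slip velocity when tau_p << dt
  Fc <- c(2e-15, -1e-15)
  st2 <- particle_step(c(0, 0), c(0, 0), dt = 1e-4, u_b = c(0, 0),
                       force = Fc, spec, eta, mode = "inertial")
  vt <- Fc / (3 * pi * eta * spec$diameter)
  expect_equal(st2$velocity, vt, tolerance = 1e-6)
  # overdamped and inertial-exponential trajectories agree for tau_p << dt
  p_o <- c(0, 0); p_i <- c(0, 0); v_i <- c(0.05, 0)
  for (s in 1:1000) {
    so <- particle_step(p_o, c(0, 0), 1e-4, c(0.05, 0), Fc, spec, eta,
                        "overdamped")
    si <- particle_step(p_i, v_i, 1e-4, c(0.05, 0), Fc, spec, eta,
                        "inertial")
    p_o <- so$position; p_i <- si$position; v_i <- si$velocity
  }
  expect_lt(max(abs(p_o - p_i)), 1e-9)
  expect_error(particle_step(c(0, 0), c(0, 0), 1e-4, c(0, 0), c(NaN, 0),
                             spec, eta), "non-finite")
})

test_that("compiled overdamped and inertial runs agree without noise", {
  cfg <- fast_config()
  cfg$brownian <- FALSE
  cfg$t_max <- 0.6
  r_o <- run_simulation(cfg)
  cfg$integrator <- "inertial"
  r_i <- run_simulation(cfg)
  expect_equal(r_o$n_captured, r_i$n_captured)
  expect_equal(r_o$eps_out, r_i$eps_out)
  live <- r_o$particles$status == "flowing" & r_i$particles$status == "flowing"
  expect_lt(max(abs(r_o$particles$x[live] - r_i$particles$x[live])), 1e-9)
  expect_lt(max(abs(r_o$particles$y[live] - r_i$particles$y[live])), 1e-9)
})

test_that("wall interaction reflects elastically or captures by the stated rule", {
  geom <- channel_geometry()
  r_h <- 60e-9
  # reflection preserves speed exactly
  st <- wall_interaction(c(0.001, -2e-8), c(0.05, -0.02), f_m = c(0, 0),
                         geom, r_h, capture_wall = -1L)
  expect_equal(st$status, "flowing")
  expect_equal(sqrt(sum(st$velocity^2)), sqrt(0.05^2 + 0.02^2),
               tolerance = 1e-12)
  expect_equal(st$position[2], 2 * r_h - (-2e-8))
  # pressed to the magnet-side wall inside the footprint -> captured
  x_fp <- mean(geom$footprint)
  st2 <- wall_interaction(c(x_fp, 1e-8), c(0.01, -1e-4),
                          f_m = c(0, -1e-15), geom, r_h, capture_wall = -1L)
  expect_equal(st2$status, "captured")
  expect_equal(st2$position[2], r_h)
  # magnet off (zero force) -> never captured
  st3 <- wall_interaction(c(x_fp, 1e-8), c(0.01, -1e-4), f_m = c(0, 0),
                          geom, r_h, capture_wall = -1L)
  expect_equal(st3$status, "flowing")
  # outside the footprint -> reflection even with wall-directed force
  st4 <- wall_interaction(c(geom$footprint[2] + 0.001, 1e-8), c(0.01, -1e-4),
                          f_m = c(0, -1e-15), geom, r_h, capture_wall = -1L)
  expect_equal(st4$status, "flowing")
  # far wall is not capture-eligible
  st5 <- wall_interaction(c(x_fp, geom$width - 1e-8), c(0.01, 1e-4),
                          f_m = c(0, 1e-15), geom, r_h, capture_wall = -1L)
  expect_equal(st5$status, "flowing")
})

test_that("capture efficiency formula and its guards", {
  expect_equal(round(capture_efficiency(3251, 3191), 2), 1.85)
  expect_equal(capture_efficiency(100, 100), 0)
  expect_equal(capture_efficiency(100, 0), 100)
  expect_error(capture_efficiency(0, 0), "undefined")
  expect_error(capture_efficiency(10, 11), "eps_out")
})

test_that("magnet off or repelled particles yield exactly zero efficiency", {
  cfg <- fast_config()
  cfg$magnet <- magnet_spec(b_rem = 0, center = c(0.028, -0.0105),
                            width = 0.044, height = 0.02)
  r0 <- run_simulation(cfg)
  expect_identical(r0$n_captured, 0L)
  expect_equal(r0$efficiency_pct, 0)
  # K < 0: magnetophoresis pushes the carriers away from the magnet-side
  # wall, so no capture event can occur with Brownian motion off
  register_material("weakmag", chi = -0.9, rho = 2000)
  cfg2 <- fast_config()
  cfg2$particle <- particle_spec("weakmag", 100e-9)
  cfg2$brownian <- FALSE
  r2 <- run_simulation(cfg2)
  expect_identical(r2$n_captured, 0L)
})

test_that("particle counts are conserved and runs replay bit-identically", {
  cfg <- fast_config()
  r1 <- run_simulation(cfg)
  expect_equal(r1$eps_in, r1$eps_out + r1$n_captured + r1$n_flowing)
  expect_equal(r1$eps_in + r1$n_never_entered, cfg$n_particles)
  r2 <- run_simulation(cfg)
  expect_identical(r1$particles, r2$particles)
  expect_identical(r1$efficiency_pct, r2$efficiency_pct)
  # the particle Reynolds guard is monitored
  expect_true(is.finite(r1$re_p_max))
  expect_gte(r1$re_p_violations, 0)
})

test_that("trajectory recording follows the requested particles", {
  cfg <- fast_config()
  cfg$t_max <- 0.3
  r <- run_simulation(cfg, record = c(1L, 5L), record_every = 20)
  tr <- r$trajectory
  expect_true(all(tr$particle %in% c(1, 5)))
  expect_true(nrow(tr) > 10)
  expect_true(all(diff(tr$t[tr$particle == 1]) > 0))
})

test_that("core-size sweep is consistent with direct runs", {
  cfg <- fast_config()
  tab <- sweep_core_size(cfg, 100e-9)
  expect_equal(nrow(tab), 1)
  cfg1 <- cfg
  cfg1$seed <- cfg$seed + 1
  direct <- run_simulation(cfg1)
  expect_equal(tab$captured, direct$n_captured)
  expect_equal(tab$efficiency_pct, direct$efficiency_pct)
  expect_error(sweep_core_size(cfg, 5e-9), "within")
})

test_that("coating sweep shares noise so a zero-thickness shell is the bare core", {
  cfg <- fast_config()
  tab <- sweep_coating(cfg, materials = c("Au", "PEG"),
                       thicknesses = c(0, 20e-9))
  expect_equal(nrow(tab), 5)  # baseline + 2 materials x 2 thicknesses
  base <- tab[tab$material == "none", ]
  z_au <- tab[tab$material == "Au" & tab$thickness_m == 0, ]
  expect_equal(z_au$captured, base$captured)
  expect_equal(z_au$efficiency_pct, base$efficiency_pct)
  expect_error(sweep_coating(cfg, thicknesses = 80e-9), "within")
})

test_that("free Brownian transport reproduces the Einstein mean-square displacement", {
  # no flow, no magnet: pure diffusion between distant walls
  cfg <- simulation_config(
    particle = particle_spec("Fe3O4", 50e-9),
    waveform = make_waveform(mean = 0, pulsatility = 0),
    magnet = magnet_spec(b_rem = 0, center = c(0.028, -0.0105),
                         width = 0.04, height = 0.02),
    n_particles = 10000, injection_times = 0, t_max = 0.05, seed = 11)
  ini <- inject(cfg)
  res <- run_simulation(cfg)
  live <- res$particles$status == "flowing"
  expect_gt(mean(live), 0.99)
  dx <- res$particles$x[live]
  dy <- res$particles$y[live] - ini$y[live]
  D_E <- KB * 310 / (3 * pi * 0.0035 * cfg$particle$diameter)
  t_eff <- cfg$t_max
  expect_equal(mean(dx^2) / (2 * D_E * t_eff), 1, tolerance = 0.05)
  expect_equal(mean(dy^2) / (2 * D_E * t_eff), 1, tolerance = 0.05)
})
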