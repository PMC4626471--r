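test_that("shipped material database matches the study properties", {
  db <- mdt_materials()
  expect_equal(material("Fe3O4")$chi, 3.1)
  expect_equal(material("Fe3O4")$rho, 5230)
  expect_equal(material("Fe2O3")$chi, 2.5)
  expect_equal(material("Fe2O3")$rho, 4890)
  expect_equal(material("Fe")$chi, 3.9)
  expect_equal(material("Fe")$rho, 7760)
  expect_equal(material("blood")$rho, 1060)
  expect_equal(material("blood")$eta, 0.0035)
  expect_equal(material("blood")$chi, -6.6e-7)
  expect_equal(material("Au")$rho, 19320)
  expect_equal(material("SiO2")$rho, 2648)
  expect_equal(material("PEG")$rho, 1114)
  expect_true(all(db$chi[db$name %in% c("Au", "SiO2", "PEG")] == 0))
  expect_error(material("unobtainium"), "unknown material")
})

test_that("Clausius-Mossotti factor matches direct evaluation and its bounds", {
  expect_equal(clausius_mossotti(0.5, 0.5), 0)
  expect_equal(clausius_mossotti(3.1), 0.5082, tolerance = 1e-3)
  expect_equal(clausius_mossotti(3.9), 0.5652, tolerance = 1e-3)
  expect_equal(clausius_mossotti(2.5), 0.4545, tolerance = 1e-3)
  chis <- c(-0.999, -0.5, 0, 1e-3, 1, 10, 1e4, 1e8)
  K <- clausius_mossotti(chis, -6.6e-7)
  expect_true(all(K >= -0.5 & K <= 1))
  expect_error(clausius_mossotti(-1.2), "exceed -1")
})

test_that("core/shell derived quantities follow spherical volume weighting", {
  bare <- particle_spec("Fe3O4", 50e-9)
  expect_identical(bare$rho_eff, 5230)
  expect_equal(bare$diameter, 100e-9)
  expect_equal(bare$mass, 5230 * 4 / 3 * pi * (50e-9)^3)
  coated <- particle_spec("Fe3O4", 50e-9, shell = "Au",
                          shell_thickness = 10e-9)
  expect_equal(coated$diameter, 120e-9)
  v_core <- 4 / 3 * pi * (50e-9)^3
  v_tot <- 4 / 3 * pi * (60e-9)^3
  expect_equal(coated$mass, 5230 * v_core + 19320 * (v_tot - v_core))
  expect_equal(coated$rho_eff, coated$mass / v_tot)
  # zero thickness is exactly the bare core
  z <- particle_spec("Fe3O4", 50e-9, shell = "PEG", shell_thickness = 0)
  expect_identical(z$rho_eff, bare$rho_eff)
  expect_error(particle_spec(core_radius = -1e-9), "positive")
})

test_that("magnetophoretic force: magnitude, cubic scaling, core-only rule", {
  spec <- particle_spec("Fe3O4", 2e-6)
  # |H| = 0.5 T / mu0 and |grad|H|| = 180 T/m / mu0 at the target
  gH2 <- c(0, -2 * (0.5 / MU0) * (180 / MU0))
  f <- magnetophoretic_force(spec, gH2)
  # independent arithmetic: 2 pi mu_b r^3 K |grad H^2|
  K <- (3.1 + 6.6e-7) / (3.1 - 2 * 6.6e-7 + 3)
  f_direct <- 2 * pi * MU0 * (1 - 6.6e-7) * (2e-6)^3 * K * abs(gH2[2])
  expect_equal(abs(f[2]), f_direct, tolerance = 1e-12)
  expect_equal(abs(f[2]), 3.7e-9, tolerance = 0.02)
  # zero gradient -> zero force
  expect_equal(as.numeric(magnetophoretic_force(spec, c(0, 0))), c(0, 0))
  # doubling the core radius multiplies the force by 8
  f2 <- magnetophoretic_force(particle_spec("Fe3O4", 4e-6), gH2)
  expect_equal(as.numeric(f2), 8 * as.numeric(f), tolerance = 1e-12)
  # a non-magnetic shell leaves the force exactly unchanged
  coated <- particle_spec("Fe3O4", 2e-6, shell = "SiO2",
                          shell_thickness = 50e-9)
  expect_identical(magnetophoretic_force(coated, gH2)[2], f[2])
})

test_that("relaxation time follows rho_eff D^2 / 18 eta", {
  spec <- particle_spec("Fe3O4", 50e-9)
  expect_equal(relaxation_time(spec, 0.0035), 5230 * (100e-9)^2 / (18 * 0.0035))
  expect_equal(relaxation_time(spec, 0.0035), 8.3e-10, tolerance = 0.01)
  spec2 <- particle_spec("Fe3O4", 100e-9)
  expect_equal(relaxation_time(spec2, 0.0035) / relaxation_time(spec, 0.0035),
               4, tolerance = 1e-12)
})

test_that("Stokes drag satisfies the m_p / tau_p = 3 pi eta D identity", {
  set.seed(5)
  for (i in 1:20) {
    r <- runif(1, 10e-9, 2e-6)
    th <- runif(1, 0, 50e-9)
    mat <- sample(c("Fe3O4", "Fe2O3", "Fe"), 1)
    sh <- sample(c("Au", "SiO2", "PEG"), 1)
    spec <- particle_spec(mat, r, shell = sh, shell_thickness = th)
    eta <- runif(1, 0.001, 0.03)
    ub <- rnorm(2); up <- rnorm(2)
    f <- drag_force(spec, ub, up, eta)
    expect_equal(as.numeric(f), 3 * pi * eta * spec$diameter * (ub - up),
                 tolerance = 1e-12)
    # drag opposes the slip velocity
    if (sum((up - ub)^2) > 0) expect_lt(sum(f * (up - ub)), 0)
  }
  spec <- particle_spec("Fe3O4", 50e-9)
  expect_equal(as.numeric(drag_force(spec, c(0.1, 0), c(0.1, 0), 0.0035)),
               c(0, 0))
})

test_that("Brownian force has the fluctuation-dissipation amplitude", {
  spec <- particle_spec("Fe3O4", 50e-9)  # r_h = 50 nm
  amp <- sqrt(12 * pi * 50e-9 * 0.0035 * KB * 310 / 1e-4)
  expect_equal(amp, 5.3e-13, tolerance = 0.01)
  set.seed(6)
  f <- brownian_force(spec, 0.0035, 310, 1e-4, n = 1e5)
  se <- amp / sqrt(1e5)
  expect_lt(abs(mean(f[, 1])), 4 * se)
  expect_lt(abs(mean(f[, 2])), 4 * se)
  expect_equal(sd(f[, 1]), amp, tolerance = 0.02)
  # amplitude depends on r_h, eta, T, dt only - not on the core material
  set.seed(7); fa <- brownian_force(particle_spec("Fe", 50e-9), 0.0035, 310, 1e-4, 1e3)
  set.seed(7); fb <- brownian_force(particle_spec("Fe3O4", 50e-9), 0.0035, 310, 1e-4, 1e3)
  expect_identical(fa, fb)
  expect_error(brownian_force(spec, 0.0035, -1, 1e-4), "positive")
})

test_that("overdamped diffusion under the Brownian force obeys the Einstein relation", {
  spec <- particle_spec("Fe3O4", 50e-9)
  eta <- 0.0035; temp <- 310; dt <- 1e-4
  drag3 <- 3 * pi * eta * spec$diameter
  D_E <- KB * temp / drag3
  n <- 1e4; nsteps <- 50
  set.seed(8)
  x <- numeric(n)
  for (s in 1:nsteps) {
    fb <- brownian_force(spec, eta, temp, dt, n = n)
    x <- x + fb[, 1] / drag3 * dt
  }
  msd <- mean(x^2)
  expect_equal(msd, 2 * D_E * nsteps * dt, tolerance = 0.05)
})
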