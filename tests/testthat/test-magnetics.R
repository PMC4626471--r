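test_that("field has the mirror symmetry of a uniformly magnetized rectangle", {
  m <- magnet_spec(b_rem = 1.2, center = c(0, 0), width = 0.02,
                   height = 0.015, axis = c(0, 1))
  set.seed(1)
  for (i in 1:20) {
    x <- runif(1, 0.011, 0.08)
    y <- runif(1, -0.05, 0.05)
    fr <- field_at(m, c(x, y))
    fl <- field_at(m, c(-x, y))
    expect_equal(fl$By, fr$By, tolerance = 1e-12)
    expect_equal(fl$Bx, -fr$Bx, tolerance = 1e-12)
  }
})

test_that("closed form matches the Biot-Savart quadrature oracle and decays as a 2D dipole", {
  m <- magnet_spec(b_rem = 1.5, center = c(0, 0), width = 0.02,
                   height = 0.012, axis = c(0, 1))
  L <- 0.02
  p10 <- c(0, 10 * L)
  p20 <- c(0, 20 * L)
  for (p in list(p10, p20, c(0.03, 0.01), c(-0.017, -0.04))) {
    bs <- biot_savart_field(m, p)
    f <- field_at(m, p)
    expect_equal(c(f$Bx, f$By), bs, tolerance = 1e-8)
  }
  b10 <- sqrt(sum(unlist(field_at(m, p10)[c("Bx", "By")])^2))
  b20 <- sqrt(sum(unlist(field_at(m, p20)[c("Bx", "By")])^2))
  expect_equal(b10 / b20, 4, tolerance = 0.05)
})

test_that("field is numerically divergence-free and curl-free at exterior points", {
  m <- magnet_spec(b_rem = 2, center = c(0.01, -0.02), width = 0.025,
                   height = 0.02, axis = c(0.3, 1))
  h <- 1e-5
  set.seed(2)
  n_checked <- 0
  while (n_checked < 100) {
    p <- c(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1))
    if (abs(p[1] - 0.01) < 0.02 || abs(p[2] + 0.02) < 0.018) next
    fx1 <- field_at(m, p + c(h, 0)); fx0 <- field_at(m, p - c(h, 0))
    fy1 <- field_at(m, p + c(0, h)); fy0 <- field_at(m, p - c(0, h))
    b <- sqrt(sum(unlist(field_at(m, p)[c("Bx", "By")])^2))
    div <- (fx1$Bx - fx0$Bx) / (2 * h) + (fy1$By - fy0$By) / (2 * h)
    curl <- (fx1$By - fx0$By) / (2 * h) - (fy1$Bx - fy0$Bx) / (2 * h)
    expect_lt(abs(div), 1e-6 * b / h)
    expect_lt(abs(curl), 1e-6 * b / h)
    n_checked <- n_checked + 1
  }
})

test_that("analytic grad |H|^2 agrees with the finite-difference oracle", {
  m <- magnet_spec(b_rem = 1, center = c(0, 0), width = 0.02, height = 0.02)
  h2 <- function(p) {
    f <- field_at(m, p)
    f$Hx^2 + f$Hy^2
  }
  h <- 1e-6
  set.seed(3)
  n_checked <- 0
  while (n_checked < 100) {
    p <- c(runif(1, -0.08, 0.08), runif(1, -0.08, 0.08))
    if (abs(p[1]) < 0.012 && abs(p[2]) < 0.012) next
    g <- grad_h2_at(m, p)
    gfd <- c((h2(p + c(h, 0)) - h2(p - c(h, 0))) / (2 * h),
             (h2(p + c(0, h)) - h2(p - c(0, h))) / (2 * h))
    expect_equal(as.numeric(g), gfd, tolerance = 1e-3)
    n_checked <- n_checked + 1
  }
  # transverse component vanishes on the symmetry axis
  g_axis <- grad_h2_at(m, c(0, 0.03))
  expect_lt(abs(g_axis[1, "gH2x"]), 1e-6 * abs(g_axis[1, "gH2y"]))
})

test_that("magnetostatics is linear in B_rem and additive over sources", {
  m1 <- magnet_spec(b_rem = 1, center = c(0, 0), width = 0.02, height = 0.02)
  p <- c(0.015, 0.04)
  f1 <- field_at(m1, p)
  for (k in c(0.5, 2)) {
    mk <- magnet_spec(b_rem = k, center = c(0, 0), width = 0.02,
                      height = 0.02)
    fk <- field_at(mk, p)
    expect_equal(c(fk$Bx, fk$By), k * c(f1$Bx, f1$By), tolerance = 1e-12)
  }
  m2 <- magnet_spec(b_rem = 0.8, center = c(0.05, -0.01), width = 0.01,
                    height = 0.03, axis = c(1, 0))
  f2 <- field_at(m2, p)
  f12 <- field_at(list(m1, m2), p)
  expect_equal(f12$Bx, f1$Bx + f2$Bx, tolerance = 1e-12)
  expect_equal(f12$By, f1$By + f2$By, tolerance = 1e-12)
})

test_that("constitutive relation B = mu0 (1 + chi_b) H holds in blood", {
  m <- magnet_spec()
  f <- field_at(m, c(0.005, 0.03), chi_b = -6.6e-7)
  mu_b <- 4e-7 * pi * (1 - 6.6e-7)
  expect_equal(f$Bx, mu_b * f$Hx, tolerance = 1e-9)
  expect_equal(f$By, mu_b * f$Hy, tolerance = 1e-9)
})

test_that("points inside the magnet are rejected with its bounds", {
  m <- magnet_spec(center = c(0, 0), width = 0.02, height = 0.02)
  expect_error(field_at(m, c(0, 0)), "inside the magnet")
  expect_error(field_at(m, c(0.009, -0.009)), "-0.01")
})

test_that("magnet_spec and blood_magnetics enforce their invariants", {
  expect_error(magnet_spec(b_rem = 2.5), "2 T")
  expect_error(magnet_spec(width = -1), "positive")
  expect_silent(blood_magnetics(-6.6e-7, alpha = 6.6, beta = -1e-7))
  expect_error(blood_magnetics(-6.6e-7, alpha = 6.6, beta = -2e-7),
               "inconsistent")
})

test_that("calibration hits the target field and gradient", {
  target <- c(0.028, 0.002)
  m0 <- pole_array_spec(b_rem = 1, n_poles = 4, center_x = 0.028,
                        face_y = -1e-4)
  cal <- calibrate_magnet(m0, target, b_target = 0.5, grad_target = 180,
                          standoff_min = 0.0021)
  v <- mdtsim:::.b_mag_and_grad(cal, target)
  expect_equal(v[["B"]], 0.5, tolerance = 0.01)
  expect_equal(v[["gradB"]], 180, tolerance = 0.05)
  expect_true(all(vapply(cal, function(m) m$b_rem, numeric(1)) <= 2))
})

test_that("calibrating to the current field is a fixed point", {
  m <- magnet_spec(b_rem = 1, center = c(0, -0.03), width = 0.004,
                   height = 0.02, axis = c(0, 1))
  v <- mdtsim:::.b_mag_and_grad(m, c(0, 0.002))
  cal <- calibrate_magnet(m, c(0, 0.002), v[["B"]], v[["gradB"]],
                          standoff_min = 0.001)
  expect_equal(cal$b_rem, m$b_rem, tolerance = 1e-6)
  expect_equal(cal$center, m$center, tolerance = 1e-6)
})

test_that("infeasible calibration reports best achievable values", {
  # a single rectangle outside a 4 mm vessel cannot reach 0.5 T with a
  # 360 1/m gradient-to-field ratio at B_rem <= 2 T
  m <- magnet_spec(b_rem = 1, center = c(0, -0.05), width = 0.004,
                   height = 0.02)
  expect_error(
    calibrate_magnet(m, c(0, 0.002), 0.5, 180, standoff_min = 0.0021),
    "calibration infeasible")
})

test_that("field grid export writes the documented CSV", {
  f <- tempfile(fileext = ".csv")
  m <- magnet_spec()
  g <- write_field_grid(m, xlim = c(-0.05, 0.05), ylim = c(0.02, 0.05),
                        n = 8, path = f)
  got <- read.csv(f)
  expect_named(got, c("x", "y", "Bx", "By", "Bmag"))
  expect_equal(nrow(got), 64)
  expect_true(all(is.finite(got$Bmag)))
  unlink(f)
})
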