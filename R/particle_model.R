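# Material database and the three forces on a core/shell magnetic carrier:
# magnetophoretic (core only), Stokes drag (whole particle), and Brownian.

.material_db <- local({
  db <- data.frame(
    name = c("blood", "Fe3O4", "Fe2O3", "Fe", "Au", "SiO2", "PEG"),
    chi  = c(-6.6e-7, 3.1, 2.5, 3.9, 0, 0, 0),
    rho  = c(1060, 5230, 4890, 7760, 19320, 2648, 1114),
    eta  = c(0.0035, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  env <- new.env(parent = emptyenv())
  assign("db", db, envir = env)
  env
})

#' Material property database
#'
#' Volume magnetic susceptibility and density of the shipped materials:
#' blood, the three magnetic core classes (magnetite Fe3O4, maghemite Fe2O3,
#' iron) and the three non-magnetic biocompatible coatings (Au, SiO2, PEG).
#'
#' @return data.frame with columns `name`, `chi`, `rho` and (for blood) `eta`.
#' @export
mdt_materials <- function() get("db", envir = .material_db)

#' Look up one material by name
#'
#' @param name material name (case sensitive).
#' @return one-row data.frame of properties.
#' @export
material <- function(name) {
  db <- mdt_materials()
  i <- match(name, db$name)
  if (is.na(i)) stop("unknown material '", name, "'; known: ",
                     paste(db$name, collapse = ", "))
  db[i, ]
}

#' Register an additional material
#'
#' @param name material name.
#' @param chi volume magnetic susceptibility (dimensionless).
#' @param rho density, kg/m^3 (must be positive).
#' @export
register_material <- function(name, chi, rho) {
  stopifnot(rho > 0, is.finite(chi))
  db <- mdt_materials()
  db <- db[db$name != name, ]
  db <- rbind(db, data.frame(name = name, chi = chi, rho = rho,
                             eta = NA_real_))
  assign("db", db, envir = .material_db)
  invisible(db)
}

#' Specify a core/shell drug carrier
#'
#' A spherical magnetic core with an optional non-magnetic biocompatible
#' shell. The magnetophoretic force acts on the core alone; drag and Brownian
#' forces see the whole particle (hydrodynamic radius = core + shell).
#' Derived quantities use spherical 3D volumes: total diameter, mass,
#' volume-weighted effective density.
#'
#' @param core core material name (must be in [mdt_materials()]).
#' @param core_radius core radius, m.
#' @param shell optional shell material name.
#' @param shell_thickness shell thickness, m (>= 0).
#' @return object of class `particle_spec`.
#' @export
particle_spec <- function(core = "Fe3O4", core_radius = 50e-9, shell = NULL,
                          shell_thickness = 0) {
  if (!is.numeric(core_radius) || core_radius <= 0)
    stop("core_radius must be positive")
  if (shell_thickness < 0) stop("shell_thickness must be >= 0")
  cm <- material(core)
  sm <- if (!is.null(shell) && shell_thickness > 0) material(shell) else NULL
  th <- if (is.null(sm)) 0 else shell_thickness
  r_h <- core_radius + th
  v_core <- 4 / 3 * pi * core_radius^3
  v_tot <- 4 / 3 * pi * r_h^3
  m_p <- cm$rho * v_core + (if (is.null(sm)) 0 else sm$rho * (v_tot - v_core))
  rho_eff <- if (is.null(sm)) cm$rho else m_p / v_tot
  structure(list(core = core, core_radius = core_radius,
                 shell = if (is.null(sm)) NULL else shell,
                 shell_thickness = th,
                 chi_core = cm$chi, rho_core = cm$rho,
                 r_h = r_h, diameter = 2 * r_h,
                 mass = m_p, rho_eff = rho_eff),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("core/shell carrier: %s core r = %.4g nm", x$core,
              1e9 * x$core_radius))
  if (!is.null(x$shell))
    cat(sprintf(" + %s shell %.4g nm", x$shell, 1e9 * x$shell_thickness))
  cat(sprintf("; D = %.4g nm, rho_eff = %.4g kg/m^3\n",
              1e9 * x$diameter, x$rho_eff))
  invisible(x)
}

#' Clausius-Mossotti factor
#'
#' Permeability contrast `K = (mu_p - mu_b) / (mu_p + 2 mu_b)` with
#' `mu = mu0 (1 + chi)`; bounded in `[-0.5, 1]` for physical media. Its sign
#' sets the direction of magnetophoresis (positive: toward increasing field).
#'
#' @param chi_p particle (core) volume susceptibility.
#' @param chi_b medium volume susceptibility.
#' @return dimensionless factor.
#' @export
clausius_mossotti <- function(chi_p, chi_b = -6.6e-7) {
  if (any(chi_p <= -1) || any(chi_b <= -1))
    stop("susceptibilities must exceed -1 (positive permeability)")
  (chi_p - chi_b) / (chi_p + 2 * chi_b + 3)
}

#' Magnetophoretic force on a core/shell particle
#'
#' `F_M = 2 pi mu_b r_core^3 K grad|H|^2`; only the magnetic core
#' contributes, so a non-magnetic shell leaves the force unchanged.
#'
#' @param spec a [particle_spec()].
#' @param grad_H2 length-2 vector (or n x 2 matrix) `grad |H|^2`, A^2/m^3.
#' @param chi_b susceptibility of the medium.
#' @return force vector(s), N, with attribute `provenance = "magnetophoretic"`.
#' @export
magnetophoretic_force <- function(spec, grad_H2, chi_b = -6.6e-7) {
  mu_b <- 4e-7 * pi * (1 + chi_b)
  K <- clausius_mossotti(spec$chi_core, chi_b)
  f <- 2 * pi * mu_b * spec$core_radius^3 * K * grad_H2
  attr(f, "provenance") <- "magnetophoretic"
  f
}

#' Particle momentum relaxation time
#'
#' `tau_p = rho_eff D^2 / (18 eta)` with the total (core + shell) diameter
#' and the volume-weighted effective density.
#'
#' @param spec a [particle_spec()].
#' @param eta dynamic viscosity, kg/(m s).
#' @return relaxation time, s.
#' @export
relaxation_time <- function(spec, eta) {
  stopifnot(eta > 0)
  spec$rho_eff * spec$diameter^2 / (18 * eta)
}

#' Stokes drag force
#'
#' `F_D = (m_p / tau_p) (u_b - u_p)`, algebraically equal to
#' `3 pi eta D (u_b - u_p)` for a sphere.
#'
#' @param spec a [particle_spec()].
#' @param u_b,u_p fluid and particle velocity, length-2 vectors (m/s).
#' @param eta dynamic viscosity, kg/(m s).
#' @return force vector, N, with attribute `provenance = "drag"`.
#' @export
drag_force <- function(spec, u_b, u_p, eta) {
  stopifnot(eta > 0)
  f <- spec$mass / relaxation_time(spec, eta) * (u_b - u_p)
  attr(f, "provenance") <- "drag"
  f
}

#' Brownian force samples
#'
#' Gaussian noise force with per-component amplitude
#' `sqrt(12 pi r_h eta k_B T / dt)`, the fluctuation paired with the Stokes
#' drag on the hydrodynamic (total) radius. Combined with mobility
#' `1 / (6 pi eta r_h)` over a step it reproduces diffusive displacements
#' `sqrt(2 D_B dt)` with `D_B = k_B T / (6 pi eta r_h)`.
#'
#' @param spec a [particle_spec()].
#' @param eta dynamic viscosity, kg/(m s).
#' @param temperature absolute temperature, K.
#' @param dt time step, s.
#' @param n number of 2D force samples to draw (uses R's RNG).
#' @return n x 2 matrix of forces, N, attribute `provenance = "brownian"`.
#' @export
brownian_force <- function(spec, eta, temperature = 310, dt = 1e-4, n = 1) {
  if (temperature <= 0 || dt <= 0)
    stop("temperature and dt must be positive")
  amp <- sqrt(12 * pi * spec$r_h * eta * 1.380649e-23 * temperature / dt)
  f <- matrix(rnorm(2 * n) * amp, ncol = 2,
              dimnames = list(NULL, c("Fx", "Fy")))
  attr(f, "provenance") <- "brownian"
  f
}
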