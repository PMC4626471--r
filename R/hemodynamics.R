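# Blood rheology (generalized power law), pulsatile inlet waveform synthesis,
# and quasi-steady velocity/shear profiles in a plane channel.

#' Generalised power-law viscosity parameters
#'
#' Shear-thinning blood rheology `eta = lambda(gdot) |gdot|^(n(gdot) - 1)`
#' with `lambda` and `n` interpolating between a low-shear power-law regime
#' (`lambda -> eta_inf + d_eta`, `n -> n_inf - d_n`) and a Newtonian plateau
#' (`eta -> eta_inf`) at high shear. Defaults are the Ballyk constants for
#' whole blood.
#'
#' @param eta_inf high-shear (Newtonian) viscosity, kg/(m s).
#' @param d_eta low-shear viscosity increment, kg/(m s).
#' @param a,b consistency transition rates, 1/s.
#' @param n_inf high-shear power-law index (Newtonian = 1).
#' @param d_n low-shear index decrement.
#' @param c,d index transition rates, 1/s.
#' @param gdot_min shear-rate floor, 1/s; the apparent viscosity diverges as
#'   `gdot^(n-1)` with `n < 1`, so shear rates are clipped from below.
#' @return object of class `viscosity_params`.
#' @export
viscosity_params <- function(eta_inf = 0.0035, d_eta = 0.025, a = 50, b = 3,
                             n_inf = 1, d_n = 0.45, c = 50, d = 4,
                             gdot_min = 1e-3) {
  stopifnot(eta_inf > 0, d_eta >= 0, a > 0, b > 0, c > 0, d > 0,
            n_inf - d_n > 0, gdot_min > 0)
  structure(list(eta_inf = eta_inf, d_eta = d_eta, a = a, b = b,
                 n_inf = n_inf, d_n = d_n, c = c, d = d,
                 gdot_min = gdot_min),
            class = "viscosity_params")
}

.visc_vec <- function(p) {
  c(p$eta_inf, p$d_eta, p$a, p$b, p$n_inf, p$d_n, p$c, p$d, p$gdot_min)
}

#' Apparent blood viscosity at a given shear rate
#'
#' @param gdot shear rate(s), 1/s; magnitudes below `params$gdot_min` are
#'   clipped.
#' @param params a [viscosity_params()].
#' @return apparent viscosity, kg/(m s).
#' @export
apparent_viscosity <- function(gdot, params = viscosity_params()) {
  if (any(!is.finite(gdot))) stop("shear rate must be finite")
  gpl_eta_cpp(as.numeric(gdot), .visc_vec(params))
}

#' Channel (vessel segment) geometry
#'
#' Straight 2D channel with walls at `y = 0` and `y = width`, flow along
#' increasing `x`. The magnet footprint is the axial interval over which wall
#' capture is possible and over which entering/leaving particles are counted.
#'
#' @param width channel width (m); default is the 4 mm inlet diameter.
#' @param length channel length (m).
#' @param footprint numeric length-2, axial extent of the magnet footprint
#'   (m); must lie within `[0, length]`.
#' @param rho_b blood density, kg/m^3.
#' @return object of class `channel_geometry`.
#' @export
channel_geometry <- function(width = 0.004, length = 0.056,
                             footprint = c(0.004, 0.052), rho_b = 1060) {
  stopifnot(width > 0, length > 0, length(footprint) == 2L,
            footprint[1] < footprint[2],
            footprint[1] >= 0, footprint[2] <= length, rho_b > 0)
  structure(list(width = width, length = length,
                 footprint = as.numeric(footprint), rho_b = rho_b),
            class = "channel_geometry")
}

#' Synthesize a pulsatile arterial inlet waveform
#'
#' Constructs the degree-9 polynomial mean-velocity waveform of one cardiac
#' cycle from its physiological landmarks: periodic continuity of value and
#' slope, a reverse-flow minimum early in the cycle, a systolic (S wave)
#' peak at roughly half the amplitude of the diastolic (D wave) peak, and a
#' prescribed cycle-average velocity. Ten linear constraints determine the
#' ten polynomial coefficients exactly, so the construction is deterministic.
#'
#' @param mean cycle-averaged velocity (m/s).
#' @param period cardiac period (s).
#' @param landmarks list with landmark times (s) `t_reverse_min`, `t_S_peak`,
#'   `t_D_peak` and relative amplitudes (multiples of `mean`) `v0_rel`
#'   (value at t = 0), `rev_rel` (reverse minimum), `S_rel` and `D_rel`
#'   (peak values). With `S_rel = D_rel / 2` the S peak sits just below half
#'   the D wave.
#' @param pulsatility scales all landmark amplitudes' deviation from the
#'   mean; 0 yields a constant waveform equal to `mean`.
#' @return object of class `flow_waveform` carrying the polynomial
#'   coefficients (ascending powers) and the landmark metadata.
#' @export
make_waveform <- function(mean = 0.10, period = 1,
                          landmarks = list(t_reverse_min = 0.12,
                                           t_S_peak = 0.35,
                                           t_D_peak = 0.85,
                                           v0_rel = 1.4, rev_rel = -0.7,
                                           S_rel = 1.6, D_rel = 3.2),
                          pulsatility = 1) {
  lm <- modifyList(list(t_reverse_min = 0.12, t_S_peak = 0.35,
                        t_D_peak = 0.85, v0_rel = 1.4, rev_rel = -0.7,
                        S_rel = 1.6, D_rel = 3.2), landmarks)
  tt <- c(lm$t_reverse_min, lm$t_S_peak, lm$t_D_peak) / period
  if (any(tt <= 0 | tt >= 1)) stop("landmark times must lie within (0, period)")
  blend <- function(rel) mean * (1 + pulsatility * (rel - 1))
  v_rev <- mean * pulsatility * lm$rev_rel + mean * (1 - pulsatility)
  v0 <- blend(lm$v0_rel); vS <- blend(lm$S_rel); vD <- blend(lm$D_rel)

  # constraints on scaled time s = t / period, coefficients c0..c9
  val <- function(s) s^(0:9)
  der <- function(s) c(0, (1:9) * s^(0:8))
  A <- rbind(val(0) - val(1),          # periodic value
             der(0) - der(1),          # periodic slope
             der(tt[1]), val(tt[1]),   # reverse-flow minimum
             der(tt[2]), val(tt[2]),   # S peak
             der(tt[3]), val(tt[3]),   # D peak
             1 / (1:10),               # cycle average
             val(0))                   # start-of-cycle value
  bvec <- c(0, 0, 0, v_rev, 0, vS, 0, vD, mean, v0)
  coef_s <- solve(A, bvec)
  coef <- coef_s / period^(0:9)        # back to unscaled time

  w <- structure(list(coef = coef, period = period, mean = mean,
                      landmarks = lm, pulsatility = pulsatility),
                 class = "flow_waveform")
  gap <- abs(mean_velocity(0, w) - mean_velocity(period, w))
  if (gap > 1e-6)
    stop("waveform fit failed periodic continuity; residual ", gap, " m/s")
  tg <- seq(0, period, length.out = 2001)
  mfit <- base::mean(mean_velocity(tg[-1], w))
  if (mean != 0 && abs(mfit - mean) / abs(mean) > 0.05)
    stop("waveform fit failed the mean constraint; fitted mean ", mfit)
  w
}

#' Evaluate the inlet mean velocity at time t
#'
#' @param t time(s), s; reduced modulo the cardiac period.
#' @param w a [make_waveform()] object.
#' @return mean inlet velocity (m/s).
#' @export
mean_velocity <- function(t, w) {
  tm <- t %% w$period
  vapply(tm, function(s) {
    v <- 0
    for (i in length(w$coef):1) v <- v * s + w$coef[i]
    v
  }, numeric(1))
}

#' Reynolds number
#'
#' @param rho fluid density, kg/m^3.
#' @param v characteristic velocity, m/s.
#' @param l characteristic length, m.
#' @param eta dynamic viscosity, kg/(m s).
#' @return `rho * v * l / eta` (dimensionless).
#' @export
reynolds <- function(rho, v, l, eta) {
  if (any(c(rho, v, l, eta) <= 0)) stop("all arguments must be positive")
  rho * v * l / eta
}

# invert the monotone stress relation tau = eta(gdot) * gdot by bisection
.gdot_from_stress <- function(tau_abs, vp) {
  lo <- rep(log(1e-10), length(tau_abs))
  hi <- rep(log(1e10), length(tau_abs))
  for (i in 1:70) {
    mid <- (lo + hi) / 2
    g <- exp(mid)
    s <- gpl_eta_cpp(g, vp) * g
    up <- s < tau_abs
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  g <- exp((lo + hi) / 2)
  g[tau_abs <= 0] <- 0
  g
}

# tabulated inverse gdot(tau), log-log interpolated; one bisection pass
# serves every subsequent profile solve
.stress_inverse <- function(vp) {
  lt <- seq(log(1e-10), log(1e7), length.out = 900)
  lg <- log(.gdot_from_stress(exp(lt), vp))
  function(tau_abs) {
    out <- numeric(length(tau_abs))
    pos <- tau_abs > 0
    out[pos] <- exp(approx(lt, lg, xout = log(tau_abs[pos]), rule = 2)$y)
    out
  }
}

# quasi-steady developed profile for mean velocity m >= 0 on a y grid:
# solve the pressure-gradient magnitude G so the cross-sectional mean matches
.profile_solve <- function(m, width, vp, y, sinv = NULL) {
  if (m <= 0) return(list(u = numeric(length(y)), gdot = numeric(length(y))))
  if (is.null(sinv)) sinv <- .stress_inverse(vp)
  h <- width / 2
  eval_G <- function(G) {
    tau <- G * abs(h - y)
    gd <- sinv(tau)
    du <- ifelse(y < h, gd, -gd)
    u <- cumsum(c(0, (du[-1] + du[-length(du)]) / 2 * diff(y)))
    mbar <- sum((u[-1] + u[-length(u)]) / 2 * diff(y)) / width
    list(u = u, gdot = gd, mean = mbar)
  }
  g_newt <- 12 * vp[1] * m / width^2
  lo <- log(g_newt * 1e-3)
  hi <- log(g_newt * 1e5)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (eval_G(exp(mid))$mean < m) lo <- mid else hi <- mid
  }
  res <- eval_G(exp((lo + hi) / 2))
  list(u = res$u, gdot = res$gdot)
}

#' Axial velocity profile across the channel
#'
#' `mode = "plug"` returns the uniform inlet profile. `mode = "developed"`
#' returns the quasi-steady fully developed profile of the shear-thinning
#' fluid driven so its cross-sectional mean equals the instantaneous waveform
#' value: the pressure gradient is found by bisection, and the pointwise
#' shear rate by inverting the monotone stress relation. No-slip holds at
#' both walls and the profile is symmetric about the centerline; a negative
#' mean reverses the profile's sign.
#'
#' @param y transverse position(s) in `[0, width]` (m).
#' @param t time (s).
#' @param geom a [channel_geometry()].
#' @param params a [viscosity_params()].
#' @param w a [make_waveform()] object.
#' @param mode `"plug"` or `"developed"`.
#' @return axial velocity (m/s) at each `y`.
#' @export
velocity_profile <- function(y, t, geom = channel_geometry(),
                             params = viscosity_params(),
                             w = make_waveform(), mode = "developed") {
  if (any(y < 0 | y > geom$width))
    stop("y outside the channel [0, ", geom$width, "]")
  m <- mean_velocity(t, w)
  if (mode == "plug") return(rep(m, length(y)))
  yg <- seq(0, geom$width, length.out = 401)
  pr <- .profile_solve(abs(m), geom$width, .visc_vec(params), yg)
  sign(m) * approx(yg, pr$u, xout = y)$y
}

# interpolation tables u(y; m), gdot(y; m) for the transport loop
.profile_tables <- function(geom, params, w, ny = 161, nm = 121) {
  tg <- seq(0, w$period, length.out = 2001)
  m_max <- max(abs(mean_velocity(tg, w))) * 1.02 + 1e-9
  m_grid <- seq(0, m_max, length.out = nm)
  y_grid <- seq(0, geom$width, length.out = ny)
  vp <- .visc_vec(params)
  sinv <- .stress_inverse(vp)
  u_tab <- matrix(0, ny, nm)
  g_tab <- matrix(0, ny, nm)
  for (j in seq_len(nm)) {
    pr <- .profile_solve(m_grid[j], geom$width, vp, y_grid, sinv)
    u_tab[, j] <- pr$u
    g_tab[, j] <- pr$gdot
  }
  list(m_grid = m_grid, y_grid = y_grid, u_tab = u_tab, g_tab = g_tab)
}

#' @importFrom stats approx
NULL
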