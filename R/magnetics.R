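# Analytic 2D magnetostatics of a rectangular permanent magnet.
#
# The exterior field of a uniformly magnetized rectangle is obtained from its
# equivalent surface current sheets (Biot-Savart closed form), which is exactly
# divergence-free and curl-free outside the magnet. The interior field is not
# modelled: the particle dynamics only ever samples points in the vessel.

.MU0 <- 4e-7 * pi

#' Specify a rectangular permanent magnet
#'
#' @param b_rem remanent flux density magnitude (T) along the magnetization
#'   axis; the equivalent magnetization is `b_rem / mu0`. Must not exceed 2 T
#'   (the strongest source considered).
#' @param center magnet center, length-2 numeric (m).
#' @param width,height rectangle extent along x and y (m).
#' @param axis magnetization axis, length-2 unit vector (normalized on input).
#' @param mu_r relative permeability of the magnet material. Only the interior
#'   constitutive relation involves it; the exterior field of the equivalent
#'   source does not, so the value is stored for fidelity but inert.
#' @return object of class `magnet_spec`.
#' @export
magnet_spec <- function(b_rem = 1, center = c(0, 0), width = 0.02,
                        height = 0.02, axis = c(0, 1), mu_r = 1.05) {
  stopifnot(is.numeric(b_rem), length(b_rem) == 1L, is.finite(b_rem),
            length(center) == 2L, all(is.finite(center)),
            length(axis) == 2L, any(axis != 0))
  if (width <= 0 || height <= 0)
    stop("magnet width and height must be positive")
  if (b_rem < 0) stop("b_rem must be non-negative")
  if (b_rem > 2)
    stop("b_rem = ", b_rem, " T exceeds the 2 T maximum source strength")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(b_rem = b_rem, center = as.numeric(center),
                 width = width, height = height, axis = axis, mu_r = mu_r),
            class = "magnet_spec")
}

#' @export
print.magnet_spec <- function(x, ...) {
  cat(sprintf(
    "rectangular magnet: B_rem = %.4g T, %.3g x %.3g cm at (%.4g, %.4g) cm, axis (%.3g, %.3g)\n",
    x$b_rem, 100 * x$width, 100 * x$height,
    100 * x$center[1], 100 * x$center[2], x$axis[1], x$axis[2]))
  invisible(x)
}

#' Blood magnetization parameters
#'
#' Blood is very weakly diamagnetic; its linearized magnetization is
#' `M = chi_b H`. When the magnetization-curve parameters `alpha` (A/m) and
#' `beta` (m/A) of the arctangent law are supplied, their product must equal
#' the linear susceptibility (`chi = alpha * beta`).
#'
#' @param chi_b volume magnetic susceptibility of blood (dimensionless).
#' @param alpha,beta optional magnetization-curve parameters.
#' @return object of class `blood_magnetics`.
#' @export
blood_magnetics <- function(chi_b = -6.6e-7, alpha = NULL, beta = NULL) {
  if (!is.null(alpha) && !is.null(beta)) {
    if (abs(alpha * beta - chi_b) / abs(chi_b) >= 1e-6)
      stop("alpha * beta = ", alpha * beta,
           " is inconsistent with chi_b = ", chi_b)
  }
  structure(list(chi_b = chi_b, alpha = alpha, beta = beta),
            class = "blood_magnetics")
}

.magnet_matrix <- function(magnet) {
  # rows: x1, x2, y1, y2, Mx, My for the C++ kernel
  m <- magnet$b_rem / .MU0
  matrix(c(magnet$center[1] - magnet$width / 2,
           magnet$center[1] + magnet$width / 2,
           magnet$center[2] - magnet$height / 2,
           magnet$center[2] + magnet$height / 2,
           m * magnet$axis[1], m * magnet$axis[2]), nrow = 1)
}

.inside_magnet <- function(magnet, pts) {
  x1 <- magnet$center[1] - magnet$width / 2
  x2 <- magnet$center[1] + magnet$width / 2
  y1 <- magnet$center[2] - magnet$height / 2
  y2 <- magnet$center[2] + magnet$height / 2
  pts[, 1] >= x1 & pts[, 1] <= x2 & pts[, 2] >= y1 & pts[, 2] <= y2
}

.as_points <- function(point) {
  if (is.null(dim(point))) {
    stopifnot(length(point) == 2L)
    point <- matrix(point, nrow = 1)
  }
  storage.mode(point) <- "double"
  point
}

#' Magnetic field sample at exterior points
#'
#' Evaluates the closed-form flux density `B`, the field strength
#' `H = B / (mu0 (1 + chi_b))` in blood, and the magnetophoretic drive term
#' `grad |H|^2` at one or more points outside the magnet.
#'
#' @param magnet a [magnet_spec()] (or a list of them, superposed).
#' @param point numeric length-2 position or an n x 2 matrix (m).
#' @param chi_b susceptibility of the surrounding medium (blood by default).
#' @return data.frame with columns `x, y, Bx, By, Hx, Hy, gH2x, gH2y`.
#' @export
field_at <- function(magnet, point, chi_b = -6.6e-7) {
  pts <- .as_points(point)
  mags <- if (inherits(magnet, "magnet_spec")) list(magnet) else magnet
  mm <- do.call(rbind, lapply(mags, .magnet_matrix))
  for (mg in mags) {
    ins <- .inside_magnet(mg, pts)
    if (any(ins))
      stop(sprintf(
        "point (%g, %g) lies inside the magnet [%g, %g] x [%g, %g]; the interior field is not modelled",
        pts[which(ins)[1], 1], pts[which(ins)[1], 2],
        mg$center[1] - mg$width / 2, mg$center[1] + mg$width / 2,
        mg$center[2] - mg$height / 2, mg$center[2] + mg$height / 2))
  }
  f <- rect_field_cpp(mm, pts)
  hf <- 1 / (.MU0 * (1 + chi_b))
  data.frame(
    x = pts[, 1], y = pts[, 2],
    Bx = f[, "Bx"], By = f[, "By"],
    Hx = f[, "Bx"] * hf, Hy = f[, "By"] * hf,
    gH2x = 2 * (f[, "Bx"] * f[, "dBxdx"] + f[, "By"] * f[, "dBydx"]) * hf^2,
    gH2y = 2 * (f[, "Bx"] * f[, "dBxdy"] + f[, "By"] * f[, "dBydy"]) * hf^2)
}

#' Gradient of the squared field strength
#'
#' Analytic `grad |H|^2` (A^2/m^3), the drive term of the magnetophoretic
#' force.
#'
#' @inheritParams field_at
#' @return n x 2 matrix with columns `gH2x`, `gH2y`.
#' @export
grad_h2_at <- function(magnet, point, chi_b = -6.6e-7) {
  f <- field_at(magnet, point, chi_b = chi_b)
  cbind(gH2x = f$gH2x, gH2y = f$gH2y)
}

.b_mag_and_grad <- function(magnet, point) {
  # |B| and grad|B| of one magnet or a superposed list (for calibration)
  pts <- .as_points(point)
  mags <- if (inherits(magnet, "magnet_spec")) list(magnet) else magnet
  mm <- do.call(rbind, lapply(mags, .magnet_matrix))
  f <- unname(rect_field_cpp(mm, pts))
  b <- sqrt(f[1, 1]^2 + f[1, 2]^2)
  gx <- (f[1, 1] * f[1, 3] + f[1, 2] * f[1, 5]) / b
  gy <- (f[1, 1] * f[1, 4] + f[1, 2] * f[1, 6]) / b
  c(B = b, gradB = sqrt(gx^2 + gy^2))
}

#' Two-pole yoke assembly
#'
#' Two adjacent rectangular magnets of opposite polarity (N and S poles side
#' by side, magnetized along +/- y), the classic high-gradient configuration:
#' flux arcs from pole to pole, so the exterior field above the assembly is
#' strong and decays on the scale of the pole gap, giving a much larger
#' gradient-to-field ratio at the vessel than a single rectangle of the same
#' strength.
#'
#' @param b_rem shared remanent flux density magnitude (T).
#' @param center_x x position of the gap center (m).
#' @param face_y y coordinate of the pole faces (m); the assembly lies below.
#' @param pole_width,pole_height dimensions of each pole (m).
#' @param gap distance between the inner pole faces (m).
#' @return list of two [magnet_spec()] objects (class `magnet_assembly`).
#' @export
pole_pair_spec <- function(b_rem = 1.5, center_x = 0, face_y = 0,
                           pole_width = 0.0058, pole_height = 0.02,
                           gap = 0.001) {
  pole_array_spec(b_rem, n_poles = 2, center_x = center_x, face_y = face_y,
                  pole_width = pole_width, pole_height = pole_height,
                  gap = gap)
}

#' Alternating pole array
#'
#' `n_poles` adjacent rectangular magnets of alternating polarity under the
#' vessel wall. For many poles the exterior field above the array approaches
#' the periodic limit `|B| ~ exp(-2 pi y / P)` with spatial period
#' `P = 2 (pole_width + gap)`, so the gradient-to-field ratio is set by the
#' pole pitch while the covered length grows with `n_poles` - the standard
#' way to extend a high-gradient capture region along a vessel.
#'
#' @inheritParams pole_pair_spec
#' @param n_poles number of poles (>= 2).
#' @return list of `n_poles` [magnet_spec()] (class `magnet_assembly`).
#' @export
pole_array_spec <- function(b_rem = 1.5, n_poles = 4, center_x = 0,
                            face_y = 0, pole_width = 0.011,
                            pole_height = 0.02, gap = 0.0008) {
  stopifnot(pole_width > 0, pole_height > 0, gap >= 0, n_poles >= 2)
  yc <- face_y - pole_height / 2
  pitch <- pole_width + gap
  span <- n_poles * pitch - gap
  x0 <- center_x - span / 2 + pole_width / 2
  out <- lapply(seq_len(n_poles) - 1, function(k)
    magnet_spec(b_rem, center = c(x0 + k * pitch, yc),
                width = pole_width, height = pole_height,
                axis = c(0, ifelse(k %% 2 == 0, 1, -1))))
  class(out) <- c("magnet_assembly", "list")
  out
}

#' Calibrate a field source to a target field and gradient
#'
#' Adjusts the stand-off distance and the remanent flux density of a magnet
#' (or rigidly of every magnet in an assembly) so that at `target_point` the
#' flux density magnitude matches `b_target` (within 1 %) and `|grad |B||`
#' matches `grad_target` (within 5 %). Because magnetostatics is linear in
#' `b_rem`, the gradient-to-field ratio depends on geometry alone: the
#' stand-off is solved first from the ratio by a 1-D root search along the
#' retreat direction, then all remanences are scaled by a common factor.
#' Magnet dimensions and relative placement are kept fixed. If the ratio
#' cannot be bracketed, or the required remanence exceeds 2 T, calibration
#' stops with the best achievable values.
#'
#' @param magnet starting [magnet_spec()] or a `magnet_assembly` /
#'   list of `magnet_spec`.
#' @param target_point length-2 position (m) where the targets are imposed,
#'   typically the vessel center.
#' @param b_target desired `|B|` (T).
#' @param grad_target desired `|grad |B||` (T/m).
#' @param standoff_min minimum distance from the nearest magnet face to the
#'   target point along the retreat direction (m); defaults to 2.1 mm so
#'   the source stays outside a 4 mm vessel. The search extends to 0.5 m.
#' @param direction unit retreat direction; defaults to the negated
#'   magnetization axis of the (first) magnet.
#' @return calibrated object of the same class as `magnet`.
#' @export
calibrate_magnet <- function(magnet, target_point, b_target, grad_target,
                             standoff_min = 2.1e-3, direction = NULL) {
  stopifnot(b_target > 0, grad_target > 0)
  single <- inherits(magnet, "magnet_spec")
  mags <- if (single) list(magnet) else magnet
  if (is.null(direction)) direction <- -mags[[1]]$axis
  direction <- direction / sqrt(sum(direction^2))

  # distance from target to each magnet's near face along -direction
  proj <- vapply(mags, function(m) {
    half <- abs(direction[1]) * m$width / 2 + abs(direction[2]) * m$height / 2
    sum((m$center - target_point) * direction) - half
  }, numeric(1))
  s_lo <- max(standoff_min - min(proj), 0)
  s_hi <- s_lo + 0.5

  shift <- function(s) {
    out <- lapply(mags, function(m) {
      m$center <- m$center + s * direction
      m
    })
    class(out) <- class(mags)
    out
  }
  ratio <- function(s) {
    v <- .b_mag_and_grad(shift(s), target_point)
    v[["gradB"]] / v[["B"]] - grad_target / b_target
  }
  # the ratio need not be monotone in the stand-off (assemblies can have
  # field nulls): locate the first sign change on a grid, then refine
  sg <- s_lo + (s_hi - s_lo) * seq(0, 1, length.out = 400)^3
  rg <- vapply(sg, ratio, numeric(1))
  ic <- which(rg[-1] * rg[-length(rg)] <= 0)
  if (!length(ic)) {
    ib <- which.min(abs(rg))
    v <- .b_mag_and_grad(shift(sg[ib]), target_point)
    stop(sprintf(
      paste0("calibration infeasible: gradient-to-field ratio %.3g 1/m is ",
             "not attainable with this geometry (closest %.3g 1/m at ",
             "stand-off shift %.3g m)"),
      grad_target / b_target, v[["gradB"]] / v[["B"]], sg[ib]))
  }
  s <- uniroot(ratio, c(sg[ic[1]], sg[ic[1] + 1]), tol = 1e-12)$root
  out <- shift(s)
  v <- .b_mag_and_grad(out, target_point)
  scale <- b_target / v[["B"]]
  b_new <- vapply(out, function(m) m$b_rem, numeric(1)) * scale
  if (any(b_new > 2)) {
    stop(sprintf(
      paste0("calibration infeasible: requires B_rem = %.3g T > 2 T; best ",
             "achievable |B| at the matched gradient ratio is %.3g T"),
      max(b_new), v[["B"]] * 2 / max(vapply(out, function(m) m$b_rem,
                                            numeric(1)))))
  }
  for (i in seq_along(out)) out[[i]]$b_rem <- b_new[i]
  if (single) out[[1]] else out
}

#' Sample the field on a regular grid and write it to CSV
#'
#' @inheritParams field_at
#' @param xlim,ylim grid extents (m).
#' @param n number of samples per axis.
#' @param path output CSV path; columns `x, y, Bx, By, Bmag`. Grid points
#'   falling inside the magnet are written as `NA`.
#' @return the sampled data.frame, invisibly.
#' @export
write_field_grid <- function(magnet, xlim, ylim, n = 50, path,
                             chi_b = -6.6e-7) {
  g <- expand.grid(x = seq(xlim[1], xlim[2], length.out = n),
                   y = seq(ylim[1], ylim[2], length.out = n))
  pts <- as.matrix(g)
  mags <- if (inherits(magnet, "magnet_spec")) list(magnet) else magnet
  ins <- Reduce(`|`, lapply(mags, .inside_magnet, pts = pts))
  out <- data.frame(x = g$x, y = g$y, Bx = NA_real_, By = NA_real_,
                    Bmag = NA_real_)
  if (any(!ins)) {
    f <- field_at(magnet, pts[!ins, , drop = FALSE], chi_b = chi_b)
    out$Bx[!ins] <- f$Bx
    out$By[!ins] <- f$By
    out$Bmag[!ins] <- sqrt(f$Bx^2 + f$By^2)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
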