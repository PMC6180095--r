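#' Monotone loading curve of a surfacing material
#'
#' Engineering strain--stress table describing the uniaxial loading
#' behaviour of a rubber-composite playground surfacing. The first point
#' must be (0, 0), strain must be strictly increasing and stress
#' non-decreasing. Between points the stress is linearly interpolated;
#' beyond the last point the last segment is extrapolated linearly.
#'
#' @param strain Dimensionless strains, strictly increasing from 0.
#' @param stress_pa Stresses in Pa, non-decreasing from 0, same length.
#' @return An object of class `material_curve`.
#' @export
material_curve <- function(strain, stress_pa) {
  strain <- as.numeric(strain)
  stress_pa <- as.numeric(stress_pa)
  if (length(strain) != length(stress_pa) || length(strain) < 2L)
    stop("strain and stress must be equal-length vectors of >= 2 points",
         call. = FALSE)
  if (strain[1L] != 0 || stress_pa[1L] != 0)
    stop("the loading curve must start at (0, 0)", call. = FALSE)
  if (any(diff(strain) <= 0))
    stop("strain must be strictly increasing", call. = FALSE)
  if (any(diff(stress_pa) < 0))
    stop("stress must be non-decreasing", call. = FALSE)
  structure(list(strain = strain, stress_pa = stress_pa),
            class = "material_curve")
}

#' Parametric rubber-composite loading curve
#'
#' Convex two-coefficient loading law `sigma(eps) = e1 * eps + e3 * eps^3`,
#' tabulated on a fine strain grid. Rubber composites load roughly linearly
#' at small strain and stiffen strongly as the porous structure compacts;
#' the cubic term captures that densification. Absolute levels of real
#' tiles are set through [calibrate_scale()], so only the shape matters
#' here.
#'
#' @param e1 Small-strain modulus in Pa.
#' @param e3 Cubic stiffening coefficient in Pa.
#' @param strain_max Largest tabulated strain.
#' @param n Number of table points.
#' @return A `material_curve`.
#' @export
parametric_rubber_curve <- function(e1 = 1.2e6, e3 = 6.0e5,
                                    strain_max = 1, n = 201L) {
  if (e1 < 0 || e3 < 0 || (e1 == 0 && e3 == 0))
    stop("`e1` and `e3` must be non-negative and not both zero", call. = FALSE)
  eps <- seq(0, strain_max, length.out = n)
  material_curve(eps, e1 * eps + e3 * eps^3)
}

#' Hysteretic surfacing material
#'
#' A loading curve plus the two parameters that govern unloading of
#' rubber/foam surfacing: the hysteretic-unloading factor `hu` (fraction of
#' the loading force retained at full unload; 1 = perfectly elastic) and
#' the `shape` exponent (curvature of the hysteresis loop). Defaults 0.5
#' and 2.0 are typical for rubber-composite playground tiles. `scale`
#' multiplies the stress ordinates and is the single knob used to make a
#' material family stiffer or softer.
#'
#' @param curve A [material_curve()].
#' @param hu Hysteretic unloading factor in (0, 1].
#' @param shape Hysteresis shape exponent, > 0.
#' @param scale Stress multiplier, > 0.
#' @return An object of class `hysteretic_material`.
#' @export
hysteretic_material <- function(curve, hu = 0.5, shape = 2.0, scale = 1.0) {
  if (!inherits(curve, "material_curve"))
    stop("`curve` must be a material_curve", call. = FALSE)
  if (!is.numeric(hu) || length(hu) != 1L || hu <= 0 || hu > 1)
    stop("`hu` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(shape) || length(shape) != 1L || shape <= 0)
    stop("`shape` must be > 0", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be > 0", call. = FALSE)
  structure(list(curve = curve, hu = hu, shape = shape, scale = scale),
            class = "hysteretic_material")
}

#' @export
print.hysteretic_material <- function(x, ...) {
  cat(sprintf(
    "<hysteretic_material> %d-point curve to strain %.3g, hu = %.3g, shape = %.3g, scale = %.4g\n",
    length(x$curve$strain), max(x$curve$strain), x$hu, x$shape, x$scale))
  invisible(x)
}

#' Baseline playground surfacing material
#'
#' The default rubber-composite material family: the parametric loading
#' curve of [parametric_rubber_curve()] with hysteretic unloading 0.5 and
#' shape factor 2.0. With the default headform and layer geometry its
#' critical fall height (HIC = 1000) is near 1.59 m, the critical height
#' of a common in-service playground tile. Stiffer and softer variants are
#' obtained with [scale_material()] (e.g. factors 5 and 1/5); all three
#' then stop the headform within the default 0.10 m layer over the height
#' range their own critical-height searches probe.
#'
#' @param scale Stress multiplier applied to the family.
#' @return A `hysteretic_material`.
#' @export
baseline_material <- function(scale = 1.0) {
  hysteretic_material(parametric_rubber_curve(), hu = 0.5, shape = 2.0,
                      scale = scale)
}

#' Scale a material's stress ordinates
#'
#' Multiplies the stress at every strain by `factor` (via the material's
#' `scale` field), leaving the strain abscissae untouched — the operation
#' used to build "5 times stiffer" and "1/5th softer" variants of a
#' baseline surfacing.
#'
#' @param m A [hysteretic_material()].
#' @param factor Positive multiplier.
#' @return A new `hysteretic_material`.
#' @export
scale_material <- function(m, factor) {
  if (!inherits(m, "hysteretic_material"))
    stop("`m` must be a hysteretic_material", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("`factor` must be a single positive number", call. = FALSE)
  hysteretic_material(m$curve, hu = m$hu, shape = m$shape,
                      scale = m$scale * factor)
}

#' Headform (drop-test missile)
#'
#' The hemispherical metal missile of impact-attenuation testing;
#' the testing-standard missile has mass 4.6 kg.
#'
#' @param mass Mass in kg.
#' @param radius Hemisphere radius in m.
#' @return An object of class `headform`.
#' @export
headform <- function(mass = 4.6, radius = 0.08) {
  if (!is.numeric(mass) || mass <= 0) stop("`mass` must be > 0", call. = FALSE)
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be > 0", call. = FALSE)
  structure(list(mass = mass, radius = radius), class = "headform")
}

#' Surfacing layer geometry
#'
#' Thickness of the surfacing tile and a cap on the plan contact area
#' (by default the headform's equatorial disc).
#'
#' @param thickness Layer thickness in m.
#' @param plan_area_cap Maximum plan contact area in m^2.
#' @return An object of class `surface_layer`.
#' @export
surface_layer <- function(thickness = 0.10, plan_area_cap = pi * 0.08^2) {
  if (!is.numeric(thickness) || thickness <= 0)
    stop("`thickness` must be > 0", call. = FALSE)
  if (!is.numeric(plan_area_cap) || plan_area_cap <= 0)
    stop("`plan_area_cap` must be > 0", call. = FALSE)
  structure(list(thickness = thickness, plan_area_cap = plan_area_cap),
            class = "surface_layer")
}

# Classed error so callers can distinguish bottoming-out from other failures.
stop_bottoming <- function(x, thickness) {
  stop(structure(class = c("playfall_bottoming", "error", "condition"),
                 list(message = sprintf(
                   paste0("bottoming out: indentation %.4g m reaches layer ",
                          "thickness %.4g m; use a stiffer curve or a ",
                          "thicker layer"), x, thickness),
                   call = NULL)))
}

# Stress at a given engineering strain: linear interpolation inside the
# table, linear extrapolation of the last segment beyond it.
stress_at_strain <- function(curve, eps) {
  strain <- curve$strain
  stress <- curve$stress_pa
  n <- length(strain)
  out <- stats::approx(strain, stress, xout = pmin(eps, strain[n]),
                       method = "linear", rule = 2)$y
  beyond <- eps > strain[n]
  if (any(beyond)) {
    slope <- (stress[n] - stress[n - 1L]) / (strain[n] - strain[n - 1L])
    out[beyond] <- stress[n] + slope * (eps[beyond] - strain[n])
  }
  out
}

# Plan area of the spherical-cap contact patch at indentation x; the cap
# geometry saturates at the hemisphere equator (x >= radius).
contact_area <- function(x, radius, plan_area_cap) {
  xe <- pmin(x, radius)
  pmin(pmax(pi * (2 * radius * xe - xe^2), 0), plan_area_cap)
}

# Loading-branch contact force at indentation x (vectorised).
loading_force <- function(x, mat, head, layer) {
  mat$scale * stress_at_strain(mat$curve, x / layer$thickness) *
    contact_area(x, head$radius, layer$plan_area_cap)
}

# Dense uniform-grid tabulation of the loading force and the stored strain
# energy W(x) = integral of F_load from 0 to x, for fast lookup inside the
# time integrator. Trapezoid on ~4k points over the layer thickness.
loading_tables <- function(mat, head, layer, n = 4096L) {
  xg <- seq(0, layer$thickness, length.out = n + 1L)
  Fg <- loading_force(xg, mat, head, layer)
  dx <- xg[2L]
  Wg <- c(0, cumsum((Fg[-1L] + Fg[-(n + 1L)]) / 2) * dx)
  list(x = xg, F = Fg, W = Wg, dx = dx, n = n + 1L,
       thickness = layer$thickness)
}

# Linear interpolation on the uniform grid of loading_tables().
table_lookup <- function(tab, x, what) {
  u <- x / tab$dx
  i <- pmin(pmax(floor(u), 0), tab$n - 2L)
  frac <- u - i
  v <- tab[[what]]
  v[i + 1L] * (1 - frac) + v[i + 2L] * frac
}

# Unloading/reloading force scale: 1 at the unloading onset (W = Wmax),
# decaying to hu as the stored energy W returns to zero.
hysteresis_scale <- function(W, Wmax, hu, shape) {
  if (Wmax <= 0 || W >= Wmax) return(1)
  r <- max(W / Wmax, 0)
  1 - (1 - hu) * (1 - r)^shape
}

#' Contact force of the hysteretic surfacing under a headform
#'
#' On loading the force is the tabulated stress at the layer strain
#' `x / thickness`, times the spherical-cap plan contact area
#' `min(pi * (2 R x - x^2), plan_area_cap)`, times the material scale.
#' On unloading (and on reloading before the stored energy regains its
#' running maximum) the loading force is multiplied by
#' `1 - (1 - hu) * (1 - W / Wmax)^shape`, where `W` is the currently
#' stored strain energy and `Wmax` its running maximum since first
#' contact: the factor is 1 at the unloading onset (force continuity)
#' and tends to `hu` as the stored energy returns to zero.
#'
#' @param state List with `indentation` (m, >= 0), `indentation_rate`
#'   (m/s), `peak_energy` (J, running max of stored strain energy) and
#'   `current_energy` (J, currently stored strain energy).
#' @param mat A [hysteretic_material()].
#' @param head A [headform()].
#' @param layer A [surface_layer()].
#' @return Contact force in N (>= 0).
#' @export
contact_force <- function(state, mat, head, layer) {
  x <- state$indentation
  if (!is.numeric(x) || x < 0)
    stop("indentation must be >= 0", call. = FALSE)
  if (x > layer$thickness)
    stop_bottoming(x, layer$thickness)
  f_load <- loading_force(x, mat, head, layer)
  s <- if (isTRUE(state$indentation_rate >= 0) &&
           state$current_energy >= state$peak_energy) 1
  else hysteresis_scale(state$current_energy, state$peak_energy,
                        mat$hu, mat$shape)
  max(f_load * s, 0)
}
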