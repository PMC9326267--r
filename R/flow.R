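#' Rectangular channel geometry
#'
#' Describes the cross-section of a rectangular microchannel. Coordinates are
#' centred on the channel midpoint: `-W/2 <= x <= W/2` across the width,
#' `-H/2 <= z <= H/2` across the height, with flow along `y`.
#'
#' @param width Channel width W in metres. Default 300 um.
#' @param height Channel height H in metres. The two chip designs used for
#'   flow-cell work are 72 um and 134 um tall; default 134 um.
#' @param length Channel length in metres (not used by the flow solution,
#'   recorded for completeness). Default 30 mm.
#' @return An object of class `channel_geometry`.
#' @examples
#' channel_geometry(300e-6, 134e-6)
#' @export
channel_geometry <- function(width = 300e-6, height = 134e-6, length = 30e-3) {
  .check_pos(width, "width"); .check_pos(height, "height")
  .check_pos(length, "length")
  structure(list(width = width, height = height, length = length),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Rectangular channel: W = %.4g um, H = %.4g um, length = %.4g mm\n",
              x$width * 1e6, x$height * 1e6, x$length * 1e3))
  invisible(x)
}

#' Fluid properties
#'
#' @param density Fluid density in kg/m^3. Default: water at 20 C (1000).
#' @param viscosity Dynamic viscosity in Pa s. Default: water at 20 C (1e-3).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1.0e-3) {
  .check_pos(density, "density"); .check_pos(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: rho = %.4g kg/m^3, mu = %.4g Pa s\n",
              x$density, x$viscosity))
  invisible(x)
}

#' Effective permeability of a rectangular duct
#'
#' Partial sum (over odd `n` up to `2 * n_terms - 1`) of the series
#' \deqn{k = \frac{W^2}{12}\left(1 - \frac{192 W}{\pi^5 H}
#'   \sum_{n\ odd} \frac{\tanh(n \pi H / 2W)}{n^5}\right),}
#' which relates the mean speed of pressure-driven laminar flow to the applied
#' pressure gradient, \eqn{U_0 = k G / \mu}. In the limit \eqn{H \to \infty}
#' the plane-Poiseuille value \eqn{W^2/12} is recovered.
#'
#' @param geometry A [channel_geometry()].
#' @param n_terms Number of series terms (odd harmonics) retained; >= 1.
#'   Ten terms give a relative truncation error below 0.1% for the channel
#'   aspect ratios used here.
#' @return Permeability k in m^2.
#' @examples
#' effective_permeability(channel_geometry(300e-6, 134e-6))
#' @export
effective_permeability <- function(geometry, n_terms = 10L) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1)
    .halt("'n_terms' must be a positive integer")
  W <- geometry$width; H <- geometry$height
  n <- seq(1, 2 * n_terms - 1, by = 2)
  W^2 / 12 * (1 - 192 * W / (pi^5 * H) * sum(tanh(n * pi * H / (2 * W)) / n^5))
}

#' Flow environment for a channel experiment
#'
#' Bundles a channel geometry, fluid, and mean (pump-set) flow speed with the
#' derived quantities needed by the flow solution: effective permeability,
#' hydraulic diameter and channel Reynolds number.
#'
#' The series solution as written already satisfies the mean-flow
#' normalization to within its truncation error; nevertheless the
#' cross-sectional mean of the evaluated field is checked by quadrature at
#' construction and, should it ever deviate from `mean_speed` by more than
#' 0.1%, the field is rescaled so that the pump-controlled mean speed is
#' honoured exactly.
#'
#' @param geometry A [channel_geometry()].
#' @param fluid A [fluid_properties()]; default water at 20 C.
#' @param mean_speed Cross-sectionally averaged flow speed U0 in m/s, as set
#'   by the syringe pump. Must be >= 0.
#' @param n_terms Series truncation (see [effective_permeability()]).
#' @return An object of class `flow_environment` with fields `geometry`,
#'   `fluid`, `mean_speed`, `permeability`, `hydraulic_diameter`, `reynolds`,
#'   `n_terms` and the internal normalization factor `scale`.
#' @examples
#' env <- flow_environment(channel_geometry(), mean_speed = 1e-3)
#' channel_velocity(0, 0, env)
#' @export
flow_environment <- function(geometry = channel_geometry(),
                             fluid = fluid_properties(),
                             mean_speed,
                             n_terms = 10L) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(fluid, "fluid_properties"))
  if (!is.numeric(mean_speed) || length(mean_speed) != 1L || mean_speed < 0)
    .halt("'mean_speed' must be a single non-negative number (m/s)")
  k <- effective_permeability(geometry, n_terms)
  if (k <= 0) .halt("series permeability is non-positive; increase 'n_terms'")
  Dh <- 2 * geometry$width * geometry$height /
    (geometry$width + geometry$height)
  env <- structure(list(geometry = geometry, fluid = fluid,
                        mean_speed = mean_speed, permeability = k,
                        hydraulic_diameter = Dh,
                        reynolds = fluid$density * mean_speed * Dh /
                          fluid$viscosity,
                        n_terms = as.integer(n_terms), scale = 1),
                   class = "flow_environment")
  # quadrature check of the mean-flow normalization (trapezoid, 201 x 101)
  if (mean_speed > 0) {
    xs <- seq(-geometry$width / 2, geometry$width / 2, length.out = 201L)
    zs <- seq(-geometry$height / 2, geometry$height / 2, length.out = 101L)
    u <- outer(xs, zs, function(x, z) channel_velocity(x, z, env))
    wx <- rep(1, 201L); wx[c(1L, 201L)] <- 0.5
    wz <- rep(1, 101L); wz[c(1L, 101L)] <- 0.5
    ubar <- sum(outer(wx, wz) * u) / sum(outer(wx, wz))
    if (abs(ubar / mean_speed - 1) > 1e-3) env$scale <- mean_speed / ubar
  }
  env
}

#' @export
print.flow_environment <- function(x, ...) {
  print(x$geometry); print(x$fluid)
  cat(sprintf("U0 = %.4g mm/s, k = %.4g m^2, D_h = %.4g um, Re_c = %.3g (%d series terms)\n",
              x$mean_speed * 1e3, x$permeability, x$hydraulic_diameter * 1e6,
              x$reynolds, x$n_terms))
  invisible(x)
}

#' Axial velocity in a rectangular channel
#'
#' Boussinesq series solution for steady pressure-driven (Poiseuille) flow in
#' a rectangular duct,
#' \deqn{u_y(x, z) = \frac{4 W^2 U_0}{\pi^3 k} \sum_{n\ odd}
#'   \frac{(-1)^{(n-1)/2}}{n^3}
#'   \left[1 - \frac{\cosh(n\pi z/W)}{\cosh(n\pi H/2W)}\right]
#'   \cos\!\left(\frac{n\pi x}{W}\right).}
#' The field vanishes on all four walls (no slip) and is symmetric in
#' `x -> -x` and `z -> -z`.
#'
#' @param x,z Coordinates in metres (vectors, recycled to a common length);
#'   must satisfy `|x| <= W/2`, `|z| <= H/2`.
#' @param env A [flow_environment()].
#' @return Axial speed u_y in m/s (same length as the inputs).
#' @export
channel_velocity <- function(x, z, env) {
  stopifnot(inherits(env, "flow_environment"))
  W <- env$geometry$width; H <- env$geometry$height
  n <- length(x) ; m <- length(z)
  if (n != m) { len <- max(n, m); x <- rep_len(x, len); z <- rep_len(z, len) }
  tol <- 1e-12
  if (any(abs(x) > W / 2 + tol * W) || any(abs(z) > H / 2 + tol * H))
    .halt("point outside the channel cross-section")
  u <- numeric(length(x))
  for (nn in seq(1, 2 * env$n_terms - 1, by = 2)) {
    u <- u + (-1)^((nn - 1) / 2) / nn^3 *
      (1 - cosh(nn * pi * z / W) / cosh(nn * pi * H / (2 * W))) *
      cos(nn * pi * x / W)
  }
  u <- 4 * W^2 * env$mean_speed / (pi^3 * env$permeability) * u * env$scale
  # clip the tiny negative truncation ripple right at the walls
  pmax(u, 0)
}

#' Channel Reynolds number
#'
#' `Re_c = rho * U0 * D_h / mu` with the hydraulic diameter
#' `D_h = 2WH/(W + H)`. At the fastest pump speeds used here this stays
#' around 0.5, well inside the laminar regime.
#'
#' @param env A [flow_environment()].
#' @return Dimensionless Reynolds number.
#' @export
channel_reynolds <- function(env) {
  stopifnot(inherits(env, "flow_environment"))
  env$reynolds
}

#' Low-Reynolds drag on a thin cylinder
#'
#' Friction coefficient (drag per unit length per unit normal speed) of an
#' infinite cylinder in slow viscous cross-flow,
#' \deqn{\xi = \frac{4 \pi \mu}{\ln(7.4 / Re)}, \qquad
#'   Re = \frac{2 \rho r u_n}{\mu},}
#' valid for `Re << 1` (the Lamb--Oseen form; the logarithm is natural). The
#' drag load per unit length is then `w = xi * u_n`.
#'
#' @param u_n Normal flow speed(s) in m/s; must be positive (a zero-speed
#'   sample carries zero load and should be handled by the caller).
#' @param radius Cylinder radius in metres.
#' @param fluid A [fluid_properties()].
#' @param warn Warn when `Re > 0.1`, where the formula starts to strain.
#' @return A data frame with columns `reynolds` and `xi` (Pa s).
#' @examples
#' drag_coefficient(1e-3, 2.2e-6, fluid_properties())
#' @export
drag_coefficient <- function(u_n, radius, fluid = fluid_properties(),
                             warn = TRUE) {
  stopifnot(inherits(fluid, "fluid_properties"))
  .check_pos(radius, "radius")
  if (!is.numeric(u_n) || any(!is.finite(u_n)) || any(u_n <= 0))
    .halt("'u_n' must be positive; zero-speed samples carry zero load")
  Re <- 2 * fluid$density * radius * u_n / fluid$viscosity
  if (any(Re >= 7.4))
    .halt("filament Reynolds number >= 7.4: outside the validity of the ",
          "low-Re drag law")
  if (warn && any(Re > 0.1))
    warning("filament Reynolds number exceeds 0.1; Re << 1 is assumed",
            call. = FALSE)
  data.frame(reynolds = Re, xi = 4 * pi * fluid$viscosity / log(7.4 / Re))
}

#' Build a flow environment from a configuration list or file
#'
#' Accepts a list (or a JSON/YAML file containing one) with fields `W_um`,
#' `H_um`, `U0_mm_s` and optionally `rho` (kg/m^3), `mu` (Pa s), `n_terms`.
#'
#' @param config A named list, or the path to a `.json`/`.yaml` file.
#' @return A [flow_environment()].
#' @export
flow_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  need <- c("W_um", "H_um", "U0_mm_s")
  if (!all(need %in% names(config)))
    .halt("config must provide fields: ", paste(need, collapse = ", "))
  flow_environment(
    channel_geometry(width = config$W_um * 1e-6, height = config$H_um * 1e-6),
    fluid_properties(density = config$rho %||% 1000,
                     viscosity = config$mu %||% 1e-3),
    mean_speed = config$U0_mm_s * 1e-3,
    n_terms = config$n_terms %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
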