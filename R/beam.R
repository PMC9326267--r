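#' Hollow elastic rod model
#'
#' A filament is modelled as a thin-walled hollow cylinder of radius `r`,
#' wall thickness `dr` and Young's modulus `E`; its bending stiffness is
#' then `beta = pi * E * r^3 * dr` (valid for `dr << r`). The constructor
#' completes whichever of `bending_stiffness`, `young_modulus` and
#' `wall_thickness` is missing from the other two (given the radius), and
#' derives `young_modulus` from a `reduced_modulus` `E* = E / (1 - nu^2)`
#' when supplied.
#'
#' @param radius Cross-section radius r (m).
#' @param young_modulus Young's modulus E (Pa), or `NULL`.
#' @param reduced_modulus Indentation (reduced) modulus E* (Pa), or `NULL`;
#'   converted via [reduced_to_young()].
#' @param wall_thickness Wall thickness dr (m), or `NULL`.
#' @param bending_stiffness Bending stiffness beta (N m^2), or `NULL`.
#' @param poisson Poisson ratio nu in [0, 1); default 0.5 (incompressible,
#'   appropriate for soft biological material).
#' @param intrinsic_curvature Stress-free reference curvature kappa0 (1/m);
#'   default 0 (straight reference).
#' @return An object of class `elastic_rod` with all consistent fields.
#' @examples
#' rod <- elastic_rod(radius = 2.2e-6, young_modulus = 40e6,
#'                    bending_stiffness = 4.8e-17)
#' rod$wall_thickness * 1e9  # nm
#' @export
elastic_rod <- function(radius, young_modulus = NULL, reduced_modulus = NULL,
                        wall_thickness = NULL, bending_stiffness = NULL,
                        poisson = 0.5, intrinsic_curvature = 0) {
  .check_pos(radius, "radius")
  if (is.null(young_modulus) && !is.null(reduced_modulus))
    young_modulus <- reduced_to_young(reduced_modulus, poisson)
  have <- c(E = !is.null(young_modulus), dr = !is.null(wall_thickness),
            beta = !is.null(bending_stiffness))
  if (sum(have) < 2L)
    .halt("give at least two of young_modulus (or reduced_modulus), ",
          "wall_thickness, bending_stiffness")
  if (!have["beta"])
    bending_stiffness <- thin_wall_stiffness(young_modulus, radius,
                                             wall_thickness)
  if (!have["dr"])
    wall_thickness <- wall_thickness(bending_stiffness, young_modulus, radius)
  if (!have["E"])
    young_modulus <- bending_stiffness / (pi * radius^3 * wall_thickness)
  .check_pos(young_modulus, "young_modulus")
  structure(list(radius = radius, young_modulus = young_modulus,
                 reduced_modulus = reduced_modulus %||%
                   (young_modulus / (1 - poisson^2)),
                 wall_thickness = wall_thickness,
                 bending_stiffness = bending_stiffness,
                 poisson = poisson,
                 intrinsic_curvature = intrinsic_curvature),
            class = "elastic_rod")
}

#' @export
print.elastic_rod <- function(x, ...) {
  cat(sprintf(paste0("Hollow elastic rod: r = %.3g um, dr = %.3g nm, ",
                     "E = %.3g MPa, beta = %.3g N m^2\n"),
              x$radius * 1e6, x$wall_thickness * 1e9,
              x$young_modulus / 1e6, x$bending_stiffness))
  invisible(x)
}

#' Bending stiffness of a thin-walled cylinder
#'
#' `beta = pi * E * r^3 * dr`, the thin-wall (`dr << r`) limit of the
#' flexural rigidity of a hollow cylinder.
#'
#' @param young_modulus Young's modulus E (Pa).
#' @param radius Cylinder radius r (m).
#' @param wall_thickness Wall thickness dr (m).
#' @return Bending stiffness in N m^2.
#' @export
thin_wall_stiffness <- function(young_modulus, radius, wall_thickness) {
  .check_pos(young_modulus, "young_modulus"); .check_pos(radius, "radius")
  .check_pos(wall_thickness, "wall_thickness")
  if (wall_thickness >= radius / 2)
    warning("wall_thickness >= radius/2: the thin-wall assumption is strained",
            call. = FALSE)
  pi * young_modulus * radius^3 * wall_thickness
}

#' Effective wall thickness from bending stiffness
#'
#' Inverts the thin-wall relation: `dr = beta / (pi * E * r^3)`. Exact
#' round-trip with [thin_wall_stiffness()].
#'
#' @param bending_stiffness Bending stiffness beta (N m^2).
#' @param young_modulus Young's modulus E (Pa).
#' @param radius Cylinder radius r (m).
#' @return Wall thickness in metres.
#' @examples
#' wall_thickness(4.8e-17, 40e6, 2.2e-6) * 1e9  # about 36 nm
#' @export
wall_thickness <- function(bending_stiffness, young_modulus, radius) {
  .check_pos(bending_stiffness, "bending_stiffness")
  .check_pos(young_modulus, "young_modulus"); .check_pos(radius, "radius")
  dr <- bending_stiffness / (pi * young_modulus * radius^3)
  if (dr >= radius / 2)
    warning("derived wall thickness >= radius/2: thin-wall assumption strained",
            call. = FALSE)
  dr
}

#' Young's modulus from an indentation (reduced) modulus
#'
#' Indentation instruments report `E* = E / (1 - nu^2)`; this returns
#' `E = E* (1 - nu^2)`.
#'
#' @param reduced_modulus E* in Pa.
#' @param poisson Poisson ratio nu in [0, 1); default 0.5.
#' @return Young's modulus in Pa.
#' @export
reduced_to_young <- function(reduced_modulus, poisson = 0.5) {
  if (!is.numeric(poisson) || length(poisson) != 1L || poisson < 0 ||
      poisson >= 1)
    .halt("'poisson' must lie in [0, 1)")
  if (any(reduced_modulus <= 0)) .halt("'reduced_modulus' must be positive")
  reduced_modulus * (1 - poisson^2)
}

#' Maximum wall stress in a bent hollow cylinder
#'
#' The peak axial stress at the outer fibre of a thin-walled cylinder bent
#' to curvature `kappa`: `sigma_s = kappa * E * r`, identically equal to
#' `kappa * beta / (pi * r^2 * dr)` whenever the rod's fields are
#' thin-wall-consistent.
#'
#' @param kappa Curvature in 1/m (>= 0).
#' @param rod An [elastic_rod()].
#' @return Stress in Pa.
#' @examples
#' max_wall_stress(470, elastic_rod(2.2e-6, 40e6, bending_stiffness = 4.8e-17))
#' @export
max_wall_stress <- function(kappa, rod) {
  stopifnot(inherits(rod, "elastic_rod"))
  if (any(kappa < 0)) .halt("'kappa' must be non-negative")
  kappa * rod$young_modulus * rod$radius
}

#' Bending energy per unit length
#'
#' `U = beta * kappa_change^2 / 2`, where `kappa_change` is the curvature
#' change away from the stress-free reference shape.
#'
#' @param bending_stiffness Bending stiffness beta (N m^2).
#' @param kappa_change Elastic curvature change (1/m).
#' @return Energy per unit length in J/m.
#' @export
bending_energy_density <- function(bending_stiffness, kappa_change) {
  .check_pos(bending_stiffness, "bending_stiffness")
  0.5 * bending_stiffness * kappa_change^2
}

#' Cantilever deflection under a distributed load
#'
#' Integrates the linearized beam equation
#' \deqn{\beta\, \delta'''' (s) = w(s)}
#' four times by cumulative trapezoids, applying free-end conditions at the
#' tip (`delta''(L) = delta'''(L) = 0`, i.e. zero moment and shear) and
#' clamped conditions at the anchor (`delta(0) = delta'(0) = 0`). This gives
#' the transverse deflection profile of a filament clamped at the channel
#' wall and loaded by flow drag. For a uniform load the result matches the
#' closed form `delta(s) = w s^2 (6 L^2 - 4 L s + s^2) / (24 beta)` (tip
#' deflection `w L^4 / 8 beta`) to discretization accuracy.
#'
#' @param s Arclength grid in metres, strictly increasing, `s[1] = 0`.
#' @param load Load per unit length w(s) in N/m, sampled on `s`.
#' @param bending_stiffness Bending stiffness beta (N m^2), > 0.
#' @return A data frame with columns `s`, `deflection` (m) and `moment`
#'   (N m, the bending moment `M = -beta * delta''`).
#' @examples
#' s <- seq(0, 250e-6, length.out = 500)
#' d <- forward_deflection(s, rep(3.9e-6, 500), 5e-17)
#' max(d$deflection)  # ~38 um
#' @export
forward_deflection <- function(s, load, bending_stiffness) {
  if (!is.numeric(bending_stiffness) || length(bending_stiffness) != 1L ||
      bending_stiffness <= 0)
    .halt("'bending_stiffness' must be a single positive number")
  if (length(s) != length(load) || length(s) < 3L)
    .halt("'s' and 'load' must be equal-length vectors with >= 3 samples")
  if (any(diff(s) <= 0)) .halt("grid error: 's' must be strictly increasing")
  wb <- load / bending_stiffness
  t1 <- pracma::cumtrapz(s, wb)                      # \int_0^s w/beta
  d3 <- t1 - t1[length(t1)]                          # delta''' (0 at s = L)
  t2 <- pracma::cumtrapz(s, d3)
  d2 <- t2 - t2[length(t2)]                          # delta''  (0 at s = L)
  d1 <- pracma::cumtrapz(s, d2)                      # delta'   (0 at s = 0)
  d0 <- pracma::cumtrapz(s, d1)                      # delta    (0 at s = 0)
  data.frame(s = s, deflection = as.numeric(d0),
             moment = as.numeric(-bending_stiffness * d2))
}
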