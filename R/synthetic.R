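# Synthetic-data generators. Every pipeline input can be generated with the
# statistical structure the analysis assumes, so each estimator can be
# validated against known ground truth without any experimental data.
# All generators are deterministic under a fixed seed (R's default
# Mersenne-Twister RNG; seeds are applied locally and do not disturb the
# caller's RNG state).

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate circular-arc filaments
#'
#' Emulates actively gliding filaments, whose shapes are close to circular
#' arcs with a broad curvature distribution. Curvatures are drawn from a
#' folded normal `|N(kappa_mean, kappa_sd)|` (a negative draw is a
#' handedness flip, folded to its magnitude), each arc is given a random
#' position and orientation, and optional isotropic Gaussian point jitter
#' emulates digitization noise.
#'
#' @param n Number of filaments.
#' @param kappa_mean,kappa_sd Curvature distribution parameters (1/m).
#'   Defaults 470 and 304, typical of actively gliding filaments.
#' @param length Contour length of each filament (m); default 1.2 mm.
#' @param spacing Sample spacing along each arc (m); default 3 um (one
#'   pixel at the shape-imaging scale).
#' @param jitter Isotropic Gaussian point noise, standard deviation in
#'   metres; default 0.
#' @param seed RNG seed or `NULL`.
#' @return List of `n` [filament_path()] objects; each carries its true
#'   curvature as attribute `"kappa_true"`.
#' @export
gen_arc_filaments <- function(n, kappa_mean = 470, kappa_sd = 304,
                              length = 1.2e-3, spacing = 3e-6,
                              jitter = 0, seed = NULL) {
  if (n < 1L) .halt("'n' must be >= 1")
  .check_pos(length, "length"); .check_pos(spacing, "spacing")
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kap <- abs(rnorm(1, kappa_mean, kappa_sd))
      s <- seq(0, length, by = spacing)
      phi0 <- runif(1, 0, 2 * pi)
      x0 <- runif(1, -5e-3, 5e-3); y0 <- runif(1, -5e-3, 5e-3)
      if (kap < 1e-9) {                      # effectively straight
        x <- x0 + s * cos(phi0); y <- y0 + s * sin(phi0)
      } else {
        R <- 1 / kap
        x <- x0 + R * (sin(phi0 + kap * s) - sin(phi0))
        y <- y0 - R * (cos(phi0 + kap * s) - cos(phi0))
      }
      if (jitter > 0) {
        x <- x + rnorm(base::length(s), 0, jitter)
        y <- y + rnorm(base::length(s), 0, jitter)
      }
      p <- filament_path(x, y)
      attr(p, "kappa_true") <- kap
      p
    })
  })
}

#' Generate planar worm-like chains
#'
#' Discrete worm-like chains confined to a plane: the tangent angle performs
#' a random walk in arclength with Gaussian increments of variance
#' `step / persistence` per step, so the tangent correlation obeys
#' `mean(cos(phi)) = exp(-ds / (2 P))` by construction. Emulates inactive
#' (chilled, non-motile) filaments, whose shapes are disordered.
#'
#' @param n Number of chains.
#' @param persistence Persistence length P (m); default 7 mm, the middle of
#'   the 5-10 mm range observed for inactive filaments.
#' @param length Contour length (m); default 3 mm.
#' @param step Discretization step (m), must be much smaller than `P`;
#'   default 10 um.
#' @param seed RNG seed or `NULL`.
#' @return List of `n` [filament_path()] objects.
#' @export
gen_wlc_filaments <- function(n, persistence = 7e-3, length = 3e-3,
                              step = 10e-6, seed = NULL) {
  if (n < 1L) .halt("'n' must be >= 1")
  .check_pos(persistence, "persistence"); .check_pos(step, "step")
  if (step >= persistence)
    .halt("resolution error: 'step' must be much smaller than 'persistence'")
  nstep <- max(2L, round(length / step))
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      th <- runif(1, 0, 2 * pi) +
        cumsum(c(0, rnorm(nstep, 0, sqrt(step / persistence))))
      x <- cumsum(c(0, step * cos(th[-base::length(th)])))
      y <- cumsum(c(0, step * sin(th[-base::length(th)])))
      filament_path(x, y)
    })
  })
}

#' Generate a synthetic flow-cell deflection experiment
#'
#' Runs the forward model with known parameters: a straight filament
#' anchored at the channel wall at height `height`, loaded by the channel
#' flow. The load and deflection are iterated to a fixed point (the load is
#' evaluated on the deflected shape, as in the analysis of real
#' experiments), the deflected configuration is rotated by `rotation` about
#' the anchor, and both configurations are perturbed with isotropic
#' Gaussian pixel noise.
#'
#' @param bending_stiffness Ground-truth stiffness beta (N m^2).
#' @param rotation Ground-truth solid-body rotation alpha (rad); default 0.
#' @param env A [flow_environment()].
#' @param radius Filament radius (m); default 2.2 um.
#' @param length Filament length in the channel (m); default 250 um. Must be
#'   less than the channel width.
#' @param height Filament height z in the channel (m); default 0 (midheight).
#' @param noise Pixel noise standard deviation in pixels; default 0.5.
#' @param pixel_scale Image scale (m/px); default 0.5 um/px.
#' @param seed RNG seed or `NULL`.
#' @param iterations Maximum load/deflection fixed-point iterations; the
#'   loop stops early once the deflection profile is converged.
#' @return A list with `experiment` (a [deflection_experiment()]) and
#'   `truth` (list: `beta`, `alpha`, `tip_deflection`).
#' @export
gen_deflection_experiment <- function(bending_stiffness, rotation = 0,
                                      env, radius = 2.2e-6, length = 250e-6,
                                      height = 0, noise = 0.5,
                                      pixel_scale = 0.5e-6, seed = NULL,
                                      iterations = 30L) {
  .check_pos(bending_stiffness, "bending_stiffness")
  stopifnot(inherits(env, "flow_environment"))
  .check_pos(radius, "radius"); .check_pos(length, "length")
  .check_pos(pixel_scale, "pixel_scale")
  W <- env$geometry$width
  if (length >= W) .halt("filament must be shorter than the channel width")
  if (abs(height) > env$geometry$height / 2)
    .halt("filament height lies outside the channel")
  s <- seq(0, length, by = pixel_scale)
  xs <- -W / 2 + s
  delta <- numeric(base::length(s))
  for (it in seq_len(iterations)) {
    defl <- filament_path(xs, delta, s = s, height = height,
                          pixel_scale = pixel_scale)
    theta <- orientation_profile(defl, window = 5L)
    uy <- channel_velocity(xs, rep(height, base::length(s)), env)
    u_n <- abs(uy * cos(theta))
    w <- numeric(base::length(s))
    pos <- u_n > 0
    if (any(pos))
      w[pos] <- drag_coefficient(u_n[pos], radius, env$fluid,
                                 warn = FALSE)$xi * u_n[pos]
    prev <- delta
    delta <- forward_deflection(s, w, bending_stiffness)$deflection
    if (env$mean_speed == 0) break
    if (max(abs(delta - prev)) < 1e-10 * max(max(delta), pixel_scale)) break
  }
  tip <- delta[base::length(delta)]
  if (tip > 0.3 * length)
    warning("tip deflection exceeds 30% of the filament length; the ",
            "small-deflection assumption is strained", call. = FALSE)
  # rotate the deflected configuration about the anchor
  ca <- cos(rotation); sa <- sin(rotation)
  ax <- xs[1L]; dx <- xs - ax
  xr <- ax + ca * dx - sa * delta
  yr <- sa * dx + ca * delta
  x0 <- xs; y0 <- rep(0, base::length(s))
  .with_seed(seed, {
    if (noise > 0) {
      sdn <- noise * pixel_scale
      x0 <- x0 + rnorm(base::length(s), 0, sdn)
      y0 <- y0 + rnorm(base::length(s), 0, sdn)
      xr <- xr + rnorm(base::length(s), 0, sdn)
      yr <- yr + rnorm(base::length(s), 0, sdn)
    }
    rest <- filament_path(x0, y0, s = s, height = height,
                          pixel_scale = pixel_scale)
    defl <- filament_path(xr, yr, s = s, height = height,
                          pixel_scale = pixel_scale)
    list(experiment = deflection_experiment(rest, defl, env, radius,
                                            height = height,
                                            pixel_scale = pixel_scale),
         truth = list(beta = bending_stiffness, alpha = rotation,
                      tip_deflection = tip))
  })
}

#' Reference parameter sets for the three study species
#'
#' Ground-truth parameter bundles (bending stiffness, moduli, curvature
#' statistics, radius, with spreads and measurement counts) for
#' *Kamptonema animale*, *Lyngbya lagerheimii* and *Oscillatoria lutea*,
#' for realistic demonstrations and for the derived-quantity pipeline.
#'
#' @return A data frame with one row per species; all quantities in SI
#'   units. Columns: `species`, then `beta`, `Estar`, `E`, `kappa`, `r`,
#'   each with `_sd` and `_n` companions.
#' @export
species_table <- function() {
  data.frame(
    species = c("K. animale", "L. lagerheimii", "O. lutea"),
    beta = c(4.8e-17, 6.0e-17, 2.6e-17),
    beta_sd = c(2.9e-17, 5.0e-17, 1.6e-17),
    beta_n = c(9L, 9L, 7L),
    Estar = c(53e6, 27e6, 35e6),
    Estar_sd = c(8e6, 6e6, 7e6),
    Estar_n = c(13L, 8L, 10L),
    E = c(40e6, 20e6, 26e6),
    E_sd = c(6e6, 4e6, 6e6),
    E_n = c(13L, 8L, 10L),
    kappa = c(470, 452, 537),
    kappa_sd = c(304, 322, 228),
    kappa_n = c(119L, 98L, 154L),
    r = c(2.2e-6, 2.2e-6, 2.1e-6),
    r_sd = c(0.1e-6, 0.1e-6, 0.1e-6),
    r_n = c(29L, 23L, 21L))
}
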