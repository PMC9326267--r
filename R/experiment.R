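# interpolate a path's coordinates onto an arclength grid given in its own
# stored parameterization
.interp_path <- function(path, sg) {
  list(x = approx(path$s, path$x, xout = sg)$y,
       y = approx(path$s, path$y, xout = sg)$y)
}

#' Flow-cell deflection experiment
#'
#' Pairs the rest and deflected configurations of a single anchored filament
#' with the flow condition that deflected it. Both paths are interpolated
#' onto a common arclength grid at one-pixel spacing (using each path's own
#' stored parameterization), truncated to the shorter contour length. The
#' paths live in channel coordinates: `x` across the width
#' (`-W/2 <= x <= W/2`), `y` along the flow, with the anchor at the channel
#' wall.
#'
#' @param rest,deflected [filament_path()] objects sharing an anchor (their
#'   first samples should coincide to within a few pixels; a larger offset
#'   triggers a warning).
#' @param flow A [flow_environment()].
#' @param radius Filament radius in metres.
#' @param height Height z of the filament in the channel (m, measured from
#'   midheight); taken from the paths when `NULL`.
#' @param pixel_scale Image pixel size (m/px); taken from the paths when
#'   `NULL`. Sets the resampling grid and the default noise floor.
#' @param id Optional label for the flow condition.
#' @return An object of class `deflection_experiment` with fields `s`
#'   (common grid), `rest`, `deflected` (resampled paths), `deflection`
#'   (observed profile `|x(s) - x0(s)|`), `flow`, `radius`, `height`,
#'   `pixel_scale`, `id`.
#' @export
deflection_experiment <- function(rest, deflected, flow, radius,
                                  height = NULL, pixel_scale = NULL,
                                  id = NA_character_) {
  stopifnot(inherits(rest, "filament_path"),
            inherits(deflected, "filament_path"),
            inherits(flow, "flow_environment"))
  .check_pos(radius, "radius")
  first_known <- function(...) {
    for (v in list(...)) if (!is.null(v) && !is.na(v)) return(v)
    NA_real_
  }
  pixel_scale <- first_known(pixel_scale, rest$pixel_scale,
                             deflected$pixel_scale)
  if (is.na(pixel_scale))
    .halt("'pixel_scale' is required (not recorded on the paths)")
  height <- first_known(height, rest$height, deflected$height)
  if (is.na(height))
    .halt("filament 'height' in the channel is required")
  H <- flow$geometry$height
  if (abs(height) > H / 2)
    .halt("filament height lies outside the channel cross-section")
  L <- min(rest$length, deflected$length)
  sg <- seq(0, L, by = pixel_scale)
  r0 <- .interp_path(rest, sg)
  r1 <- .interp_path(deflected, sg)
  anchor_gap <- sqrt((r1$x[1] - r0$x[1])^2 + (r1$y[1] - r0$y[1])^2)
  if (anchor_gap > 3 * pixel_scale)
    warning(sprintf(
      "rest and deflected anchors differ by %.3g px; paths may be misaligned",
      anchor_gap / pixel_scale), call. = FALSE)
  # digitization noise can push wall-adjacent samples marginally outside
  # the cross-section; tolerate a few pixels, reject anything further out
  W <- flow$geometry$width
  if (any(abs(r1$x) > W / 2 + 5 * pixel_scale) ||
      any(abs(r0$x) > W / 2 + 5 * pixel_scale))
    .halt("filament extends outside the channel cross-section")
  rest_rs <- filament_path(r0$x, r0$y, s = sg, height = height,
                           pixel_scale = pixel_scale)
  defl_rs <- filament_path(r1$x, r1$y, s = sg, height = height,
                           pixel_scale = pixel_scale)
  structure(list(s = sg, rest = rest_rs, deflected = defl_rs,
                 deflection = sqrt((r1$x - r0$x)^2 + (r1$y - r0$y)^2),
                 flow = flow, radius = radius, height = height,
                 pixel_scale = pixel_scale, id = id),
            class = "deflection_experiment")
}

#' @export
print.deflection_experiment <- function(x, ...) {
  cat(sprintf(paste0("Deflection experiment%s: L = %.4g um, U0 = %.3g mm/s, ",
                     "tip deflection %.3g um\n"),
              if (is.na(x$id)) "" else paste0(" [", x$id, "]"),
              max(x$s) * 1e6, x$flow$mean_speed * 1e3,
              x$deflection[length(x$deflection)] * 1e6))
  invisible(x)
}

#' Hydrodynamic load along a deflected filament
#'
#' Evaluates the far-field channel flow at each sample of the deflected
#' path (at the filament's height), projects it onto the local normal
#' (tangents from a total-least-squares fit over a `window`-sample sliding
#' window), and converts the normal speed to a drag load per unit length via
#' the low-Reynolds cylinder friction coefficient: `w(s) = xi(s) u_n(s)`.
#' Samples with zero normal speed carry zero load.
#'
#' @param experiment A [deflection_experiment()].
#' @param window Tangent-fit window in samples (pixels); default 5, the
#'   tight window used for flow-cell work.
#' @param warn Passed to [drag_coefficient()].
#' @return A data frame with columns `s`, `u_n` (m/s), `reynolds`, `xi`
#'   (Pa s) and `load` (N/m).
#' @export
normal_flow_load <- function(experiment, window = 5L, warn = TRUE) {
  stopifnot(inherits(experiment, "deflection_experiment"))
  theta <- orientation_profile(experiment$deflected, window = window)
  W <- experiment$flow$geometry$width
  xq <- pmin(pmax(experiment$deflected$x, -W / 2), W / 2)
  uy <- channel_velocity(xq, rep(experiment$height, length(experiment$s)),
                         experiment$flow)
  u_n <- abs(uy * cos(theta))
  out <- data.frame(s = experiment$s, u_n = u_n, reynolds = 0, xi = NA_real_,
                    load = 0)
  pos <- u_n > 0
  if (any(pos)) {
    dc <- drag_coefficient(u_n[pos], experiment$radius,
                           experiment$flow$fluid, warn = warn)
    out$reynolds[pos] <- dc$reynolds
    out$xi[pos] <- dc$xi
    out$load[pos] <- dc$xi * u_n[pos]
  }
  out
}
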