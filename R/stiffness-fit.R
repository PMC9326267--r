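#' Fit bending stiffness and solid-body rotation to a deflection experiment
#'
#' The core inverse procedure. The observed deflected shape is decomposed
#' into a bending mode and a small solid-body rotation about the anchor:
#' the drag load is evaluated along the deflected path
#' ([normal_flow_load()]), integrated to a unit-stiffness bending profile
#' `c(s)` ([forward_deflection()] with `beta = 1`), and the parameters
#' `(beta, alpha)` minimize the cost
#' \deqn{\sum_s \left(c(s)/\beta - |x(s) - R(\alpha) x_0(s)|\right)^2,}
#' where `R(alpha)` rotates the rest configuration about the anchor point.
#' For fixed `alpha` the optimal stiffness is available in closed form,
#' `beta = sum(c^2) / sum(c * delta_corr)`, so `alpha` is found by a
#' bounded one-dimensional search of the profiled residual. With
#' `allow_rotation = FALSE` all motion is attributed to bending
#' (`alpha = 0`), which yields a lower bound on the stiffness.
#'
#' A per-point stiffness profile `beta(s) = c(s) / delta_corr(s)` is also
#' returned (the stiffness that would reproduce the observed bending of each
#' individual sample), retained only where the corrected deflection exceeds
#' the noise floor and outside the near-clamp region where the ratio
#' degenerates; its mean and standard deviation summarize the per-test
#' spread.
#'
#' If the optimal rotation absorbs the entire deflection (pure-rotation
#' data), the stiffness is unbounded: `beta = Inf` is returned with a
#' warning.
#'
#' @param experiment A [deflection_experiment()].
#' @param allow_rotation Fit the rotation angle (default) or pin `alpha = 0`.
#' @param max_rotation Half-width of the rotation search interval, radians;
#'   default 5 degrees.
#' @param noise_floor Minimum corrected deflection (m) for a sample to enter
#'   the per-point profile; default `2 * pixel_scale`.
#' @param clamp_exclude Fraction of the contour length next to the clamp
#'   excluded from the per-point profile; default 0.1.
#' @param window Tangent window (samples) for the load evaluation.
#' @return An object of class `stiffness_fit` with components `beta` (N m^2),
#'   `alpha` (rad), `profile` (data frame: `s`, `delta_obs`, `delta_pred`,
#'   `beta_local`), `beta_mean`, `beta_sd`, `n_points` (per-point summary),
#'   `residual` (RMS misfit, m), `experiment`, `load`, and the settings used.
#' @seealso [pointwise_stiffness()], [aggregate_strand()],
#'   [gen_deflection_experiment()]
#' @examples
#' env <- flow_environment(channel_geometry(), mean_speed = 1e-3)
#' syn <- gen_deflection_experiment(5e-17, 0, env, noise = 0, seed = 1)
#' fit <- fit_filament_stiffness(syn$experiment)
#' coef(fit)
#' @export
fit_filament_stiffness <- function(experiment, allow_rotation = TRUE,
                                   max_rotation = 5 * pi / 180,
                                   noise_floor = NULL, clamp_exclude = 0.1,
                                   window = 5L) {
  stopifnot(inherits(experiment, "deflection_experiment"))
  if (is.null(noise_floor)) noise_floor <- 2 * experiment$pixel_scale
  .check_pos(noise_floor, "noise_floor")
  load <- normal_flow_load(experiment, window = window, warn = FALSE)
  cprof <- forward_deflection(experiment$s, load$load, 1)$deflection
  if (max(cprof) <= 0)
    .halt("no-signal error: the flow exerts no load on the filament")
  if (max(experiment$deflection) < noise_floor)
    .halt("no-signal error: observed deflection is below the noise floor")
  x0 <- experiment$rest$x; y0 <- experiment$rest$y
  xd <- experiment$deflected$x; yd <- experiment$deflected$y
  ax <- x0[1L]; ay <- y0[1L]
  dcorr <- function(alpha) {
    ca <- cos(alpha); sa <- sin(alpha)
    xr <- ax + ca * (x0 - ax) - sa * (y0 - ay)
    yr <- ay + sa * (x0 - ax) + ca * (y0 - ay)
    sqrt((xd - xr)^2 + (yd - yr)^2)
  }
  cc2 <- sum(cprof^2)
  profiled <- function(alpha) {
    d <- dcorr(alpha)
    sum(d^2) - max(sum(cprof * d), 0)^2 / cc2
  }
  alpha <- 0
  if (allow_rotation) {
    opt <- optimize(profiled, c(-max_rotation, max_rotation), tol = 1e-8)
    alpha <- opt$minimum
  }
  d <- dcorr(alpha)
  scd <- sum(cprof * d)
  if (scd <= 0) {
    warning("deflection is fully absorbed by the rotation mode; ",
            "bending stiffness is unbounded", call. = FALSE)
    beta <- Inf
  } else {
    beta <- cc2 / scd
  }
  delta_p <- if (is.finite(beta)) cprof / beta else rep(0, length(cprof))
  keep <- d >= noise_floor & experiment$s >= clamp_exclude * max(experiment$s)
  beta_local <- rep(NA_real_, length(d))
  beta_local[keep] <- cprof[keep] / d[keep]
  retained <- beta_local[keep & is.finite(beta)]
  structure(list(
    beta = beta, alpha = alpha,
    profile = data.frame(s = experiment$s, delta_obs = d,
                         delta_pred = delta_p, beta_local = beta_local),
    beta_mean = if (length(retained)) mean(retained) else NA_real_,
    beta_sd = if (length(retained) > 1L) sd(retained) else NA_real_,
    n_points = length(retained),
    residual = sqrt(mean((delta_p - d)^2)),
    experiment = experiment, load = load,
    unit_profile = cprof, noise_floor = noise_floor,
    allow_rotation = allow_rotation, clamp_exclude = clamp_exclude),
    class = "stiffness_fit")
}

#' Per-point stiffness profile of a completed fit
#'
#' Recomputes `beta(s) = c(s) / delta_corr(s)` with a caller-chosen noise
#' floor, returning the retained profile and its mean and standard
#' deviation.
#'
#' @param fit A [fit_filament_stiffness()] result.
#' @param noise_floor Minimum corrected deflection (m); defaults to the
#'   fit's own floor.
#' @param clamp_exclude Near-clamp exclusion fraction; defaults to the
#'   fit's own setting.
#' @return A list with `profile` (data frame `s`, `beta_local` of retained
#'   samples), `mean`, `sd`, `n`.
#' @export
pointwise_stiffness <- function(fit, noise_floor = NULL,
                                clamp_exclude = NULL) {
  stopifnot(inherits(fit, "stiffness_fit"))
  noise_floor <- noise_floor %||% fit$noise_floor
  clamp_exclude <- clamp_exclude %||% fit$clamp_exclude
  d <- fit$profile$delta_obs
  keep <- d >= noise_floor & fit$profile$s >= clamp_exclude * max(fit$profile$s)
  if (!any(keep))
    .halt("no-signal error: all samples fall below the noise floor")
  bl <- fit$unit_profile[keep] / d[keep]
  list(profile = data.frame(s = fit$profile$s[keep], beta_local = bl),
       mean = mean(bl), sd = if (length(bl) > 1L) sd(bl) else NA_real_,
       n = length(bl))
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("Stiffness fit: beta = %.4g N m^2, alpha = %.3g deg, RMS residual = %.3g um\n",
              x$beta, x$alpha * 180 / pi, x$residual * 1e6))
  invisible(x)
}

#' @export
summary.stiffness_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.stiffness_fit")
}

#' @export
print.summary.stiffness_fit <- function(x, ...) {
  f <- x$fit; e <- f$experiment
  cat("Flow-cell bending stiffness fit\n")
  cat(sprintf("  filament: L = %.4g um, r = %.3g um, height z = %.3g um\n",
              max(e$s) * 1e6, e$radius * 1e6, e$height * 1e6))
  cat(sprintf("  flow: U0 = %.3g mm/s, channel %g x %g um, Re_c = %.3g\n",
              e$flow$mean_speed * 1e3, e$flow$geometry$width * 1e6,
              e$flow$geometry$height * 1e6, e$flow$reynolds))
  cat(sprintf("  beta  = %.4g N m^2%s\n", f$beta,
              if (f$allow_rotation) "" else "  (rotation pinned to 0: lower bound)"))
  cat(sprintf("  alpha = %.4g deg\n", f$alpha * 180 / pi))
  cat(sprintf("  per-point beta: mean %.4g, sd %.3g N m^2 over %d samples\n",
              f$beta_mean, f$beta_sd, f$n_points))
  cat(sprintf("  RMS residual: %.3g um (tip deflection %.3g um)\n",
              f$residual * 1e6,
              f$profile$delta_obs[nrow(f$profile)] * 1e6))
  invisible(x)
}

#' @export
coef.stiffness_fit <- function(object, ...) {
  c(beta = object$beta, alpha = object$alpha)
}

#' @export
fitted.stiffness_fit <- function(object, ...) object$profile$delta_pred

#' @export
residuals.stiffness_fit <- function(object, ...) {
  object$profile$delta_obs - object$profile$delta_pred
}

#' Predicted deflection profile
#'
#' Deflection predicted by the fitted load profile at a given stiffness
#' (the fitted value by default), on the experiment's arclength grid.
#'
#' @param object A `stiffness_fit`.
#' @param bending_stiffness Stiffness to predict at; default the fitted one.
#' @param ... Unused.
#' @return Numeric vector of deflections (m) on `object$profile$s`.
#' @export
predict.stiffness_fit <- function(object, bending_stiffness = NULL, ...) {
  b <- bending_stiffness %||% object$beta
  if (!is.finite(b) || b <= 0) .halt("'bending_stiffness' must be positive")
  object$unit_profile / b
}

#' @export
plot.stiffness_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4.2, 4.2, 2, 1))
  on.exit(par(op))
  e <- x$experiment
  plot(e$rest$x * 1e6, e$rest$y * 1e6, type = "l", col = "grey50",
       xlab = "x (um)", ylab = "y (um)", main = "configurations", asp = 1)
  lines(e$deflected$x * 1e6, e$deflected$y * 1e6, col = "steelblue", lwd = 2)
  legend("topleft", c("rest", "deflected"), col = c("grey50", "steelblue"),
         lwd = c(1, 2), bty = "n", cex = 0.8)
  plot(x$profile$s * 1e6, x$profile$delta_obs * 1e6, pch = 16, cex = 0.4,
       xlab = "s (um)", ylab = "deflection (um)", main = "fit")
  lines(x$profile$s * 1e6, x$profile$delta_pred * 1e6, col = "firebrick",
        lwd = 2)
  legend("topleft", c("observed (rotation-corrected)", "predicted"),
         col = c("black", "firebrick"), pch = c(16, NA), lty = c(NA, 1),
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate replicate experiments from a fitted model
#'
#' Parametric resampling: regenerates synthetic deflection experiments at
#' the fitted `(beta, alpha)` under the experiment's own flow condition and
#' geometry, with Gaussian pixel noise.
#'
#' @param object A `stiffness_fit`.
#' @param nsim Number of replicates.
#' @param seed RNG seed (integer) or `NULL`.
#' @param noise Pixel noise standard deviation in pixels; default 0.5.
#' @param ... Unused.
#' @return A list of `nsim` synthetic experiments (see
#'   [gen_deflection_experiment()]).
#' @export
simulate.stiffness_fit <- function(object, nsim = 1, seed = NULL,
                                   noise = 0.5, ...) {
  if (!is.finite(object$beta))
    .halt("cannot simulate from an unbounded stiffness")
  e <- object$experiment
  seeds <- if (is.null(seed)) sample.int(2^31 - 2, nsim)
           else seed + seq_len(nsim) - 1L
  lapply(seeds, function(sd_i)
    gen_deflection_experiment(object$beta, object$alpha, e$flow,
                              radius = e$radius, length = max(e$s),
                              height = e$height, noise = noise,
                              pixel_scale = e$pixel_scale, seed = sd_i))
}

#' Error-weighted strand and species aggregation
#'
#' `aggregate_strand()` combines the per-test fits of one filament strand
#' (its different flow conditions) into a representative stiffness by an
#' inverse-variance weighted mean, with weights `1 / sd^2` from the
#' per-point standard deviations; if any test reports zero variance the
#' weights are undefined and an unweighted mean is used with a warning.
#' `aggregate_species()` then averages the strand values without weights,
#' reporting the population mean, standard deviation and count.
#'
#' @param fits A list of `stiffness_fit` objects, or a data frame with
#'   columns `beta` and `beta_sd`.
#' @return `aggregate_strand()`: list with `beta`, `se` (standard error of
#'   the weighted mean) and `n`.
#' @examples
#' aggregate_strand(data.frame(beta = c(4, 8), beta_sd = c(1, 2)))$beta  # 4.8
#' @export
aggregate_strand <- function(fits) {
  if (is.data.frame(fits)) {
    beta <- fits$beta; sds <- fits$beta_sd
  } else {
    stopifnot(all(vapply(fits, inherits, TRUE, "stiffness_fit")))
    beta <- vapply(fits, function(f) f$beta, 0)
    sds <- vapply(fits, function(f) f$beta_sd, 0)
  }
  if (length(beta) == 0L) .halt("no fits to aggregate")
  if (length(beta) == 1L)
    return(list(beta = beta, se = sds, n = 1L))
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    warning("zero or undefined per-test variance; falling back to an ",
            "unweighted mean", call. = FALSE)
    return(list(beta = mean(beta), se = sd(beta) / sqrt(length(beta)),
                n = length(beta)))
  }
  w <- 1 / sds^2
  list(beta = sum(w * beta) / sum(w), se = sqrt(1 / sum(w)),
       n = length(beta))
}

#' @param strand_betas Numeric vector of per-strand stiffness values.
#' @return `aggregate_species()`: list with `beta` (mean), `sd` and `n`.
#' @rdname aggregate_strand
#' @export
aggregate_species <- function(strand_betas) {
  strand_betas <- strand_betas[is.finite(strand_betas)]
  if (length(strand_betas) == 0L) .halt("no strand values to aggregate")
  list(beta = mean(strand_betas),
       sd = if (length(strand_betas) > 1L) sd(strand_betas) else NA_real_,
       n = length(strand_betas))
}
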