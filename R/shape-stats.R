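#' Tangent-angle correlation of a filament ensemble
#'
#' For each contour separation `ds`, the mean of
#' `cos(theta(s + ds) - theta(s))` over all sample pairs in all filaments
#' (every pair weighted equally). Orientation profiles are computed with the
#' wide shape-statistics tangent window (90 um by default). Separations are
#' binned at `bin_width` resolution up to `max_sep` (half the longest
#' contour by default, beyond which bins are noise-dominated). The zero
#' separation bin is identically 1.
#'
#' For straight filaments the correlation is 1 everywhere; for a single
#' circular arc of curvature `kappa` it equals `cos(kappa * ds)`; for planar
#' worm-like chains of persistence length `P` it decays as
#' `exp(-ds / (2 P))` (the factor 2 is the surface-confined convention).
#'
#' @param paths A list of [filament_path()] objects (or a single path).
#' @param bin_width Separation bin width in metres; default 90 um, matching
#'   the tangent window.
#' @param max_sep Largest separation retained (m); default half the longest
#'   contour length.
#' @param window_length Tangent-fit window in metres; default 90 um,
#'   converted to samples on each path's grid.
#' @return An object of class `angular_correlation`: a data frame with
#'   columns `sep` (bin centre, m), `mean_cos`, `n_pairs`, `min`, `max`
#'   (per-bin envelope).
#' @export
angular_correlation <- function(paths, bin_width = 90e-6, max_sep = NULL,
                                window_length = 90e-6) {
  if (inherits(paths, "filament_path")) paths <- list(paths)
  if (length(paths) == 0L) .halt("size error: empty filament ensemble")
  stopifnot(all(vapply(paths, inherits, TRUE, "filament_path")))
  .check_pos(bin_width, "bin_width")
  if (is.null(max_sep))
    max_sep <- max(vapply(paths, function(p) p$length, 0)) / 2
  nb <- max(1L, ceiling(max_sep / bin_width))
  sums <- counts <- numeric(nb)
  lo <- rep(Inf, nb); hi <- rep(-Inf, nb)
  for (p in paths) {
    h <- mean(diff(p$s))
    win <- max(2L, round(window_length / h))
    if (length(p$s) <= win) next
    th <- orientation_profile(p, window = win)
    n <- length(th)
    kmax <- min(n - 1L, floor(max_sep / h))
    for (k in seq_len(kmax)) {
      ds <- k * h
      b <- min(nb, max(1L, ceiling(ds / bin_width)))
      cphi <- cos(th[(1L + k):n] - th[1L:(n - k)])
      sums[b] <- sums[b] + sum(cphi)
      counts[b] <- counts[b] + length(cphi)
      lo[b] <- min(lo[b], min(cphi)); hi[b] <- max(hi[b], max(cphi))
    }
  }
  if (all(counts == 0)) .halt("size error: no admissible sample pairs")
  keep <- counts > 0
  out <- data.frame(sep = c(0, (which(keep) - 0.5) * bin_width),
                    mean_cos = c(1, sums[keep] / counts[keep]),
                    n_pairs = c(NA_integer_, counts[keep]),
                    min = c(1, lo[keep]), max = c(1, hi[keep]))
  class(out) <- c("angular_correlation", "data.frame")
  out
}

#' Persistence length from a tangent-angle correlation
#'
#' Nonlinear least-squares fit of the surface-confined worm-like-chain decay
#' `mean_cos = exp(-ds / (2 P))` to the binned correlation, in linear space
#' with equal bin weights (log-space fitting breaks down when bins approach
#' zero). The single parameter `P` is profiled by a bounded one-dimensional
#' minimization.
#'
#' @param corr An [angular_correlation()] (or data frame with `sep` and
#'   `mean_cos`).
#' @return An object of class `persistence_fit`: list with `persistence`
#'   (m), `n_bins`, `sse` and the input `corr`.
#' @export
fit_persistence_length <- function(corr) {
  sep <- corr$sep; mc <- corr$mean_cos
  pos <- sep > 0
  if (sum(pos & mc > 0) < 3L)
    .halt("fit error: need at least 3 populated bins with positive correlation")
  if (all(mc[pos] <= 0)) .halt("fit error: all correlations non-positive")
  sse <- function(P) sum((mc - exp(-sep / (2 * P)))^2)
  smax <- max(sep)
  opt <- optimize(sse, interval = c(smax * 1e-4, smax * 1e5),
                  tol = smax * 1e-10)
  structure(list(persistence = opt$minimum, n_bins = sum(pos),
                 sse = opt$objective, corr = corr),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("Persistence length: P = %.4g mm (%d bins, SSE %.3g)\n",
              x$persistence * 1e3, x$n_bins, x$sse))
  invisible(x)
}

#' @export
coef.persistence_fit <- function(object, ...) {
  c(persistence = object$persistence)
}

#' @export
plot.persistence_fit <- function(x, ...) {
  plot(x$corr$sep * 1e3, x$corr$mean_cos, pch = 16,
       xlab = expression(Delta * s ~ "(mm)"),
       ylab = expression(group(langle, cos ~ phi, rangle)), ylim = c(0, 1))
  polygon(c(x$corr$sep, rev(x$corr$sep)) * 1e3,
          c(x$corr$min, rev(x$corr$max)),
          col = adjustcolor("grey", 0.4), border = NA)
  ss <- seq(0, max(x$corr$sep), length.out = 200)
  lines(ss * 1e3, exp(-ss / (2 * x$persistence)), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Per-filament curvature statistics of an ensemble
#'
#' Global curvature of each filament either from a Pratt circle fit to the
#' whole path (`method = "circle"`, the default used for gliding filaments,
#' which are close to circular arcs) or as the mean absolute local curvature
#' `|d theta / d s|` (`method = "local"`). Circle-fit curvatures are signed
#' by the filament's net turning direction (counter-clockwise positive), so
#' ensembles with no preferred handedness centre on zero, while the local
#' method reports an unsigned bending magnitude.
#'
#' @param paths List of [filament_path()] objects.
#' @param method `"circle"` or `"local"`.
#' @param window_length Tangent window (m) for the orientation fits.
#' @return A list with `per_filament` (data frame: `curvature` in 1/m,
#'   `length` in m), `mean`, `sd`, `median`, `n`.
#' @export
curvature_statistics <- function(paths, method = c("circle", "local"),
                                 window_length = 90e-6) {
  if (inherits(paths, "filament_path")) paths <- list(paths)
  if (length(paths) == 0L) .halt("size error: empty filament ensemble")
  method <- match.arg(method)
  kap <- vapply(paths, function(p) {
    h <- mean(diff(p$s))
    win <- max(2L, round(window_length / h))
    th <- orientation_profile(p, window = win)
    if (method == "circle") {
      turn <- th[base::length(th)] - th[1L]
      sign_turn <- if (turn < 0) -1 else 1
      sign_turn * pratt_circle_fit(p)$curvature
    } else {
      mean(abs(curvature_profile(th, p$s)))
    }
  }, 0)
  lens <- vapply(paths, function(p) p$length, 0)
  list(per_filament = data.frame(curvature = kap, length = lens),
       mean = mean(kap), sd = if (length(kap) > 1L) sd(kap) else NA_real_,
       median = median(kap), n = length(kap))
}

#' Energy scales of filament shape fluctuations
#'
#' Two scales built from a bending stiffness: the incoherent strain energy
#' density `U = beta / P^2` implied by shape disorder of persistence length
#' `P`, and the thermal persistence length `P_T = beta / (k_B T)` the
#' filament would have if its shape were set by thermal fluctuations alone
#' (kilometres for micron-scale filaments, showing the shapes are actively
#' generated).
#'
#' @param bending_stiffness Bending stiffness beta (N m^2).
#' @param persistence Measured persistence length P (m).
#' @param temperature Temperature in kelvin; default 293 K (20 C culture
#'   conditions).
#' @return A list with `energy_density` (J/m) and `thermal_persistence` (m).
#' @examples
#' energy_scales(5e-17, 7e-3)$energy_density  # about 1e-12 J/m
#' @export
energy_scales <- function(bending_stiffness, persistence,
                          temperature = 293) {
  .check_pos(bending_stiffness, "bending_stiffness")
  .check_pos(persistence, "persistence")
  .check_pos(temperature, "temperature")
  list(energy_density = bending_stiffness / persistence^2,
       thermal_persistence = bending_stiffness / (.kB * temperature))
}
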