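#' Arclength-parameterized filament path
#'
#' A digitized filament centreline in the plane. Arclength `s` starts at the
#' first point (the anchor, for flow-cell experiments) and is computed as the
#' cumulative chord length unless supplied.
#'
#' @param x,y Point coordinates in metres.
#' @param s Optional arclength samples in metres; must be strictly
#'   increasing. Computed from the points when `NULL`.
#' @param height Optional height z of the filament in the channel (m).
#' @param pixel_scale Optional pixel size of the source image (m/px).
#' @return An object of class `filament_path` with fields `s`, `x`, `y`,
#'   `height`, `pixel_scale` and `length` (total contour length, m).
#' @seealso [orientation_profile()], [curvature_profile()],
#'   [resample_path()], [read_filament_csv()]
#' @export
filament_path <- function(x, y, s = NULL, height = NA_real_,
                          pixel_scale = NA_real_) {
  if (length(x) != length(y) || length(x) < 2L)
    .halt("'x' and 'y' must be equal-length vectors with >= 2 points")
  if (is.null(s)) {
    s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  } else {
    if (length(s) != length(x)) .halt("'s' must match the number of points")
    if (any(diff(s) <= 0)) .halt("'s' must be strictly increasing")
    s <- s - s[1L]
  }
  structure(list(s = as.numeric(s), x = as.numeric(x), y = as.numeric(y),
                 height = height, pixel_scale = pixel_scale,
                 length = s[length(s)] - s[1L]),
            class = "filament_path")
}

#' @export
print.filament_path <- function(x, ...) {
  cat(sprintf("Filament path: %d samples, contour length %.4g um",
              length(x$s), x$length * 1e6))
  if (!is.na(x$height)) cat(sprintf(", height %.4g um", x$height * 1e6))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.filament_path <- function(x, ...) {
  data.frame(s_m = x$s, x_m = x$x, y_m = x$y)
}

#' Resample a path at uniform arclength spacing
#'
#' Linear interpolation of the coordinates versus arclength, then
#' re-accumulation of `s` from the resampled chords so the parameterization
#' stays consistent. Total length is preserved to within one sample spacing.
#'
#' @param path A [filament_path()].
#' @param spacing Target spacing in metres, or `NULL` to use `n`.
#' @param n Number of samples (used when `spacing` is `NULL`).
#' @return A [filament_path()] on a uniform grid.
#' @export
resample_path <- function(path, spacing = NULL, n = NULL) {
  stopifnot(inherits(path, "filament_path"))
  if (is.null(spacing) && is.null(n)) .halt("give either 'spacing' or 'n'")
  if (is.null(n)) n <- max(2L, round(path$length / spacing) + 1L)
  sg <- seq(0, path$length, length.out = n)
  xg <- approx(path$s, path$x, xout = sg)$y
  yg <- approx(path$s, path$y, xout = sg)$y
  filament_path(xg, yg, height = path$height, pixel_scale = path$pixel_scale)
}

# wrap angles to (-pi, pi]
.wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- a[a <= -pi] + 2 * pi
  a
}

#' Tangent orientation along a filament
#'
#' The tangent angle theta(s) at every sample, from a total-least-squares
#' (principal-axis) line fit over a sliding window of neighbouring samples.
#' A principal axis is only defined modulo pi, so each fitted direction is
#' oriented along the local secant and the resulting angle sequence is
#' unwrapped to remove +-pi ambiguities and +-2 pi jumps; theta is therefore
#' continuous and can drift outside (-pi, pi] for strongly curved paths.
#'
#' Two window conventions are in use: a tight 5-sample window at pixel
#' resolution for flow-cell normal-load evaluation, and a wide 30-pixel
#' (90 um at 3 um/px) window for population shape statistics.
#'
#' @param path A [filament_path()].
#' @param window Window size in samples (>= 2); samples within
#'   `ceiling(window/2)` of each end use a clamped (one-sided) window.
#' @return Numeric vector theta(s) in radians, one value per sample.
#' @export
orientation_profile <- function(path, window = 5L) {
  stopifnot(inherits(path, "filament_path"))
  n <- length(path$s)
  window <- as.integer(window)
  if (window < 2L) .halt("'window' must be >= 2 samples")
  if (n <= window) .halt("path has too few samples for the requested window")
  hw <- window %/% 2L
  theta <- numeric(n)
  for (i in seq_len(n)) {
    j0 <- max(1L, i - hw); j1 <- min(n, i + hw)
    xs <- path$x[j0:j1]; ys <- path$y[j0:j1]
    cx <- xs - mean(xs); cy <- ys - mean(ys)
    # principal axis of the 2x2 scatter matrix, closed form
    sxx <- sum(cx * cx); syy <- sum(cy * cy); sxy <- sum(cx * cy)
    ang <- 0.5 * atan2(2 * sxy, sxx - syy)
    tx <- cos(ang); ty <- sin(ang)
    # orient along the local secant
    dx <- path$x[j1] - path$x[j0]; dy <- path$y[j1] - path$y[j0]
    if (tx * dx + ty * dy < 0) { tx <- -tx; ty <- -ty }
    theta[i] <- atan2(ty, tx)
  }
  theta[1L] + cumsum(c(0, .wrap_pi(diff(theta))))
}

#' Curvature profile from a tangent-angle profile
#'
#' `kappa(s) = d theta / d s` by central finite differences at interior
#' samples and one-sided differences at the ends. The mean of the returned
#' profile equals `(theta(L) - theta(0)) / L` up to discretization error.
#'
#' @param theta Unwrapped tangent angles (radians), as returned by
#'   [orientation_profile()].
#' @param s Arclength samples (m), strictly increasing, same length.
#' @return Signed curvature in 1/m (counter-clockwise positive).
#' @export
curvature_profile <- function(theta, s) {
  n <- length(theta)
  if (n < 3L) .halt("need at least 3 samples to differentiate")
  if (length(s) != n || any(diff(s) <= 0))
    .halt("'s' must be strictly increasing and match 'theta'")
  k <- numeric(n)
  k[1L] <- (theta[2L] - theta[1L]) / (s[2L] - s[1L])
  k[n] <- (theta[n] - theta[n - 1L]) / (s[n] - s[n - 1L])
  i <- 2:(n - 1L)
  k[i] <- (theta[i + 1L] - theta[i - 1L]) / (s[i + 1L] - s[i - 1L])
  k
}

#' Curvature along a path
#'
#' Convenience wrapper: [orientation_profile()] followed by
#' [curvature_profile()].
#'
#' @inheritParams orientation_profile
#' @return Signed curvature in 1/m at every sample.
#' @export
path_curvature <- function(path, window = 5L) {
  curvature_profile(orientation_profile(path, window), path$s)
}

#' Algebraic circle fit (Pratt normalization)
#'
#' Fits the circle `a(x^2+y^2) + b x + c y + d = 0` minimizing the algebraic
#' distance under the Pratt constraint `b^2 + c^2 - 4 a d = 1`, solved as a
#' generalized eigenvalue problem. The fit is exact on noiseless circles and
#' degrades gracefully on near-collinear data, returning a very large radius
#' (curvature -> 0) rather than failing.
#'
#' @param x,y Point coordinates (m), or a [filament_path()] as first
#'   argument.
#' @return A list with `center` (length-2, m), `radius` (m) and `curvature`
#'   (1/m, unsigned; 0 for exactly collinear input).
#' @examples
#' t <- seq(0, pi / 3, length.out = 50)
#' f <- pratt_circle_fit(2e-3 * cos(t), 2e-3 * sin(t))
#' f$curvature  # 500 1/m
#' @export
pratt_circle_fit <- function(x, y = NULL) {
  if (inherits(x, "filament_path")) { y <- x$y; x <- x$x }
  if (length(x) != length(y) || length(x) < 3L)
    .halt("need at least 3 points for a circle fit")
  # centre and scale for numerical conditioning
  mx <- mean(x); my <- mean(y)
  sc <- sqrt(mean((x - mx)^2 + (y - my)^2))
  if (sc == 0) .halt("degenerate input: all points coincide")
  u <- (x - mx) / sc; v <- (y - my) / sc
  z <- u^2 + v^2
  Z <- cbind(z, u, v, 1)
  M <- crossprod(Z) / length(x)
  # Pratt constraint matrix B: b^2 + c^2 - 4 a d = 1
  Binv <- matrix(c(0, 0, 0, -0.5,
                   0, 1, 0, 0,
                   0, 0, 1, 0,
                   -0.5, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(Binv %*% M)
  lam <- Re(ev$values); vec <- Re(ev$vectors)
  # smallest non-negative eigenvalue (zero for an exact circle)
  ok <- which(lam > -sqrt(.Machine$double.eps) * max(abs(lam), 1))
  if (length(ok) == 0L) .halt("circle fit failed: no admissible eigenvalue")
  p <- vec[, ok[which.min(lam[ok])]]
  a <- p[1L]; b <- p[2L]; cc <- p[3L]; d <- p[4L]
  disc <- b^2 + cc^2 - 4 * a * d
  if (abs(a) < 1e-14 * sqrt(abs(disc))) {
    # collinear limit: a straight line
    return(list(center = c(NA_real_, NA_real_), radius = Inf, curvature = 0))
  }
  cx <- -b / (2 * a); cy <- -cc / (2 * a)
  r <- sqrt(max(disc, 0)) / (2 * abs(a))
  list(center = c(cx * sc + mx, cy * sc + my),
       radius = r * sc,
       curvature = 1 / (r * sc))
}
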