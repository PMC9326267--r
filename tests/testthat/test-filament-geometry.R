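make_arc <- function(R = 2e-3, span = 0.5, n = 400, phi0 = 0) {
  th <- seq(0, span, length.out = n)
  filament_path(R * sin(phi0 + th) - R * sin(phi0),
                -R * cos(phi0 + th) + R * cos(phi0))
}

test_that("orientation profiles are exact on straight paths and linear on arcs", {
  s <- seq(0, 1e-3, length.out = 200)
  p45 <- filament_path(s / sqrt(2), s / sqrt(2))
  th <- orientation_profile(p45, window = 5)
  expect_equal(th, rep(pi / 4, 200), tolerance = 1e-10)
  # arc of curvature 0.5 / mm: theta linear in s with that slope (interior)
  arc <- make_arc(R = 2e-3, span = 0.5, n = 500)
  th <- orientation_profile(arc, window = 5)
  i <- 20:480
  slope <- coef(lm(th[i] ~ arc$s[i]))[2]
  expect_equal(unname(slope), 500, tolerance = 0.02)
  # reversing the parameterization negates the curvature
  rev_arc <- filament_path(rev(arc$x), rev(arc$y))
  k_fwd <- path_curvature(arc, window = 5)
  k_rev <- path_curvature(rev_arc, window = 5)
  expect_equal(mean(k_fwd[i]), -mean(rev(k_rev)[i]), tolerance = 1e-6)
  expect_error(orientation_profile(filament_path(1:3 * 1e-6, rep(0, 3)),
                                   window = 5), "few samples")
})

test_that("curvature profiles differentiate the orientation correctly", {
  s <- seq(0, 1e-3, length.out = 1000)
  # linear theta: constant curvature equal to the slope
  expect_equal(curvature_profile(470 * s, s), rep(470, 1000))
  expect_equal(curvature_profile(rep(1.2, 1000), s), rep(0, 1000))
  # sinusoidal theta: matches the analytic derivative to < 1%
  th <- 0.3 * sin(2 * pi * s / 1e-3)
  k <- curvature_profile(th, s)
  k_true <- 0.3 * 2 * pi / 1e-3 * cos(2 * pi * s / 1e-3)
  i <- 2:999
  expect_lt(max(abs(k[i] - k_true[i])) / max(abs(k_true)), 0.01)
  # mean equals the endpoint slope up to discretization
  arc <- make_arc(R = 2e-3, span = 0.4, n = 800)
  th <- orientation_profile(arc, window = 5)
  k <- curvature_profile(th, arc$s)
  expect_equal(mean(k), (th[800] - th[1]) / arc$length, tolerance = 5e-3)
  expect_error(curvature_profile(c(0, 1), c(0, 1)), "3 samples")
})

test_that("Pratt circle fit is exact on circles and safe on degenerate input", {
  t <- seq(0.3, 0.3 + 2 * pi * 0.8, length.out = 50)
  f <- pratt_circle_fit(1.3e-3 + 2e-3 * cos(t), -0.4e-3 + 2e-3 * sin(t))
  expect_equal(f$radius, 2e-3, tolerance = 1e-12)
  expect_equal(f$curvature, 500, tolerance = 1e-12)
  expect_equal(f$center, c(1.3e-3, -0.4e-3), tolerance = 1e-9)
  # collinear input: effectively straight
  f0 <- pratt_circle_fit(seq(0, 1e-3, length.out = 30),
                         2 * seq(0, 1e-3, length.out = 30))
  expect_lt(f0$curvature, 1e-6)
  expect_error(pratt_circle_fit(c(0, 1e-6), c(0, 0)), "3 points")
})

test_that("Pratt fit tracks the geometric least-squares oracle on noisy arcs", {
  set.seed(42)
  R <- 2e-3
  ratios <- replicate(100, {
    t <- seq(0, pi / 6, length.out = 60)  # 30 degree arc
    x <- R * cos(t) + rnorm(60, 0, 3e-6)
    y <- R * sin(t) + rnorm(60, 0, 3e-6)
    c(pratt_circle_fit(x, y)$radius, geometric_circle_fit(x, y)$radius)
  })
  expect_lt(abs(median(ratios[1, ]) / R - 1), 0.05)
  # algebraic and geometric fits agree closely case by case
  expect_lt(median(abs(ratios[1, ] / ratios[2, ] - 1)), 0.02)
})

test_that("curvature estimates are invariant to resampling and rigid motions", {
  arc <- make_arc(R = 2e-3, span = 0.6, n = 300)
  k0 <- pratt_circle_fit(arc)$curvature
  rs <- resample_path(arc, n = 211)
  expect_equal(pratt_circle_fit(rs)$curvature, k0, tolerance = 0.01)
  expect_equal(rs$length, arc$length, tolerance = 1e-4)
  # rotation + translation
  a <- 0.7
  xr <- 1e-3 + cos(a) * arc$x - sin(a) * arc$y
  yr <- -2e-3 + sin(a) * arc$x + cos(a) * arc$y
  rot <- filament_path(xr, yr)
  expect_equal(pratt_circle_fit(rot)$radius, 1 / k0, tolerance = 1e-12)
  expect_equal(path_curvature(rot, 7), path_curvature(arc, 7),
               tolerance = 1e-9)
  # local and global curvature agree on arcs subtending <= 90 degrees
  th <- orientation_profile(arc, window = 7)
  k_local <- mean(curvature_profile(th, arc$s))
  expect_equal(abs(k_local), k0, tolerance = 0.03)
})

test_that("skeleton tracing recovers straight segments and arcs from rasters", {
  # straight segment, 300 um long, 5 px wide
  st <- filament_path(seq(0, 300e-6, length.out = 200), rep(0, 200))
  img <- rasterize_filament(st, 1.5e-6, width = 5 * 1.5e-6)
  tr <- trace_skeleton(img, 1.5e-6)
  expect_gt(tr$length, 285e-6)
  expect_lt(tr$length, 315e-6)
  expect_lt(max(abs(path_curvature(tr, window = 15))), 50)
  # arc R = 2 mm traced at the 3 um/px shape-imaging scale
  arc <- make_arc(R = 2e-3, span = 0.5, n = 500)
  img2 <- rasterize_filament(arc, 3e-6, width = 9e-6)
  tr2 <- trace_skeleton(img2, 3e-6)
  expect_equal(tr2$length, arc$length, tolerance = 0.05)
  kfit <- pratt_circle_fit(tr2)$curvature
  expect_gt(kfit, 480); expect_lt(kfit, 520)
  # same path at a finer pixel scale gives consistent physical results
  img3 <- rasterize_filament(arc, 1.5e-6, width = 9e-6)
  tr3 <- trace_skeleton(img3, 1.5e-6)
  expect_equal(pratt_circle_fit(tr3)$curvature, kfit, tolerance = 0.03)
})

test_that("skeleton tracing rejects malformed images", {
  blob <- matrix(FALSE, 40, 40)
  blob[5:10, 5:10] <- TRUE
  blob[25:30, 25:30] <- TRUE
  expect_error(trace_skeleton(blob, 1e-6), "multiple connected components")
  expect_error(trace_skeleton(matrix(FALSE, 10, 10), 1e-6), "no foreground")
  # a genuine Y-branch whose arms are too long to prune as spurs
  y <- matrix(FALSE, 61, 61)
  y[31, 1:31] <- TRUE      # west arm
  y[31:61, 31] <- TRUE     # south arm
  y[1:31, 31] <- TRUE      # north arm
  expect_error(trace_skeleton(y, 1e-6), "endpoints")
})
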