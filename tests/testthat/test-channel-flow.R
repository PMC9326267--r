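test_that("effective permeability matches the series value and its limits", {
  geom <- channel_geometry(300e-6, 134e-6)
  k <- effective_permeability(geom, 10)
  expect_equal(k, 1.076e-9, tolerance = 1e-3)
  # contributions shrink monotonically with the number of retained terms
  ks <- vapply(1:8, function(n) effective_permeability(geom, n), 0)
  expect_true(all(diff(abs(diff(ks))) < 0))
  # wide-channel limit: plane Poiseuille between plates of separation W
  wide <- channel_geometry(300e-6, 0.5)
  expect_equal(effective_permeability(wide, 40), (300e-6)^2 / 12,
               tolerance = 1e-6)
  expect_error(channel_geometry(-1e-6, 1e-4), "positive")
})

test_that("permeability and velocity agree with a finite-difference Poisson oracle", {
  for (dims in list(c(300e-6, 134e-6), c(100e-6, 100e-6))) {
    fd <- fd_duct_flow(dims[1], dims[2], n = 201L)
    k <- effective_permeability(channel_geometry(dims[1], dims[2]), 10)
    expect_equal(k, fd$k, tolerance = 5e-3)
    env <- flow_environment(channel_geometry(dims[1], dims[2]),
                            mean_speed = 1e-3)
    # compare on an interior sub-grid, relative to the centreline speed
    ix <- seq(21L, 181L, by = 20L)
    u_pkg <- outer(fd$x[ix], fd$z[ix],
                   function(x, z) channel_velocity(x, z, env))
    u_fd <- fd$u_over_U0[ix, ix] * 1e-3
    expect_lt(max(abs(u_pkg - u_fd)) / max(u_fd), 5e-3)
  }
})

test_that("velocity field obeys no-slip, symmetry and mean-flow normalization", {
  env <- flow_environment(channel_geometry(300e-6, 134e-6), mean_speed = 1e-3)
  W <- 300e-6; H <- 134e-6
  zs <- seq(-H / 2, H / 2, length.out = 11)
  xs <- seq(-W / 2, W / 2, length.out = 11)
  # no-slip on all four walls, at every truncation
  for (nt in c(1L, 3L, 10L)) {
    e <- flow_environment(channel_geometry(W, H), mean_speed = 1e-3,
                          n_terms = nt)
    expect_true(all(abs(channel_velocity(rep(W / 2, 11), zs, e)) < 1e-12))
    expect_true(all(abs(channel_velocity(rep(-W / 2, 11), zs, e)) < 1e-12))
    expect_true(all(abs(channel_velocity(xs, rep(H / 2, 11), e)) < 1e-12))
    expect_true(all(abs(channel_velocity(xs, rep(-H / 2, 11), e)) < 1e-12))
  }
  # reflection symmetry
  x <- runif(20, 0, W / 2); z <- runif(20, 0, H / 2)
  expect_equal(channel_velocity(x, z, env), channel_velocity(-x, z, env))
  expect_equal(channel_velocity(x, z, env), channel_velocity(x, -z, env))
  # centreline speed (frozen from an independent series evaluation,
  # cross-checked against the finite-difference oracle above)
  expect_equal(channel_velocity(0, 0, env), 1.958e-3, tolerance = 1e-3)
  # cross-sectional mean equals U0 to < 0.1% at 10 terms (trapezoid quadrature)
  n <- 301L
  xs <- seq(-W / 2, W / 2, length.out = n)
  zs <- seq(-H / 2, H / 2, length.out = n)
  u <- outer(xs, zs, function(x, z) channel_velocity(x, z, env))
  wq <- rep(1, n); wq[c(1, n)] <- 0.5
  ubar <- sum(outer(wq, wq) * u) / sum(outer(wq, wq))
  expect_equal(ubar, 1e-3, tolerance = 1e-3)
  expect_error(channel_velocity(W, 0, env), "outside")
})

test_that("wide channels recover the plane-Poiseuille midwidth profile", {
  # At aspect ratio 10 the midwidth profile has the plane-Poiseuille
  # parabolic shape; its amplitude sits ~6% above 1.5 U0 because the
  # side-wall boundary layers depress the cross-sectional mean (confirmed
  # by the finite-difference oracle), so shape and amplitude are checked
  # separately.
  H <- 100e-6
  env <- flow_environment(channel_geometry(10 * H, H), mean_speed = 1e-3)
  n <- 81L
  z <- seq(-H / 2, H / 2, length.out = n)
  u <- channel_velocity(rep(0, n), z, env)
  wq <- rep(1, n); wq[c(1, n)] <- 0.5
  shape <- u / (sum(wq * u) / sum(wq))
  expect_lt(max(abs(shape - 1.5 * (1 - (2 * z / H)^2))) / 1.5, 0.02)
  expect_gt(channel_velocity(0, 0, env), 1.5e-3)
  expect_lt(channel_velocity(0, 0, env), 1.65e-3)
})

test_that("channel Reynolds number uses the hydraulic diameter and is linear in U0", {
  env <- flow_environment(channel_geometry(300e-6, 134e-6),
                          mean_speed = 2.59e-3)
  expect_equal(channel_reynolds(env), 0.48, tolerance = 5e-3)
  expect_equal(round(channel_reynolds(env), 1), 0.5)
  expect_equal(channel_reynolds(
    flow_environment(channel_geometry(), mean_speed = 0)), 0)
  env2 <- flow_environment(channel_geometry(300e-6, 134e-6),
                           mean_speed = 2 * 2.59e-3)
  expect_equal(channel_reynolds(env2), 2 * channel_reynolds(env))
})

test_that("cylinder drag follows the log-law friction coefficient", {
  water <- fluid_properties()
  dc <- drag_coefficient(1e-3, 2.2e-6, water)
  expect_equal(dc$reynolds, 4.4e-3)
  expect_equal(dc$xi, 4 * pi * 1e-3 / log(7.4 / 4.4e-3))
  expect_equal(dc$xi, 1.69e-3, tolerance = 2e-3)
  # the study's own fastest condition
  dc2 <- drag_coefficient(2.6e-3, 2.2e-6, water)
  expect_equal(dc2$reynolds, 0.01144, tolerance = 1e-6)
  # monotonically increasing with normal speed
  u <- c(1e-4, 1e-3, 1e-2)
  expect_true(all(diff(drag_coefficient(u, 2.2e-6, water)$xi) > 0))
  expect_error(drag_coefficient(0, 2.2e-6, water), "positive")
  expect_error(drag_coefficient(2, 2.2e-6, water), "7.4")
  expect_warning(drag_coefficient(0.03, 2.2e-6, water), "0.1")
})

test_that("flow environments can be built from config lists", {
  env <- flow_from_config(list(W_um = 300, H_um = 134, U0_mm_s = 1))
  expect_equal(env$geometry$width, 300e-6)
  expect_equal(env$mean_speed, 1e-3)
  expect_equal(env$n_terms, 10L)
  expect_error(flow_from_config(list(W_um = 300)), "config")
})
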