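test_that("normal flow load projects the channel flow onto the filament normal", {
  env <- test_flow_env(U0 = 1e-3)
  W <- env$geometry$width
  px <- 0.5e-6
  # straight filament perpendicular to the flow at midheight:
  # u_n equals the midplane velocity profile along x
  s <- seq(0, 250e-6, by = px)
  rest <- filament_path(-W / 2 + s, rep(0, length(s)), s = s, height = 0,
                        pixel_scale = px)
  exp0 <- deflection_experiment(rest, rest, env, radius = 2.2e-6)
  ld <- normal_flow_load(exp0)
  expect_equal(ld$u_n, channel_velocity(rest$x, rep(0, length(s)), env),
               tolerance = 1e-10)
  expect_true(all(ld$load >= 0))
  # filament parallel to the flow: no normal component, no load
  par_rest <- filament_path(rep(-W / 2 + 50e-6, length(s)), s, s = s,
                            height = 0, pixel_scale = px)
  exp_par <- deflection_experiment(par_rest, par_rest, env, radius = 2.2e-6)
  ld_par <- normal_flow_load(exp_par)
  i <- 10:(length(s) - 10)  # clamped tangent windows at the ends
  expect_lt(max(ld_par$u_n[i]), 1e-12)
  expect_lt(max(ld_par$load[i]), 1e-15)
  # 45-degree filament: u_n = u / sqrt(2)
  s45 <- seq(0, 150e-6, by = px)
  p45 <- filament_path(-W / 2 + s45 / sqrt(2), s45 / sqrt(2), s = s45,
                       height = 0, pixel_scale = px)
  exp45 <- deflection_experiment(p45, p45, env, radius = 2.2e-6)
  ld45 <- normal_flow_load(exp45)
  u_at <- channel_velocity(p45$x, rep(0, length(s45)), env)
  expect_equal(ld45$u_n[i], u_at[i] / sqrt(2), tolerance = 0.01)
})

test_that("stiffness is recovered exactly from noiseless synthetic experiments", {
  # grid over stiffness and flow speed; self-consistency of the inverse
  for (beta in c(1e-17, 3e-17, 1e-16)) {
    for (U0 in c(0.5e-3, 2.6e-3)) {
      env <- test_flow_env(U0 = U0)
      syn <- suppressWarnings(
        gen_deflection_experiment(beta, 0, env, noise = 0, seed = 1))
      fit <- fit_filament_stiffness(syn$experiment)
      expect_lt(abs(fit$beta / beta - 1), 0.01)
      expect_lt(abs(fit$alpha) * 180 / pi, 0.02)
    }
  }
})

test_that("stiffness and rotation are recovered under pixel noise", {
  env <- test_flow_env(U0 = 0.5e-3)
  beta_true <- 2.6e-17; alpha_true <- 0.5 * pi / 180
  res <- vapply(1:50, function(i) {
    syn <- gen_deflection_experiment(beta_true, alpha_true, env,
                                     noise = 0.5, seed = 1000 + i)
    fit <- fit_filament_stiffness(syn$experiment)
    c(fit$beta, fit$alpha)
  }, c(0, 0))
  expect_lt(abs(median(res[1, ]) / beta_true - 1), 0.10)
  expect_lt(abs(median(res[2, ]) - alpha_true) * 180 / pi, 0.1)
})

test_that("neglecting rotation yields a lower-bound stiffness and larger residual", {
  env <- test_flow_env(U0 = 1e-3)
  syn <- gen_deflection_experiment(5e-17, 0.5 * pi / 180, env, noise = 0,
                                   seed = 3)
  fit_rot <- fit_filament_stiffness(syn$experiment, allow_rotation = TRUE)
  fit_fix <- fit_filament_stiffness(syn$experiment, allow_rotation = FALSE)
  expect_lte(fit_fix$beta, fit_rot$beta)
  expect_lte(fit_rot$residual, fit_fix$residual + 1e-15)
  expect_equal(fit_rot$alpha, 0.5 * pi / 180, tolerance = 0.01)
})

test_that("pure rotation data is identified as unbounded stiffness", {
  env <- test_flow_env(U0 = 1e-3)
  W <- env$geometry$width; px <- 0.5e-6
  s <- seq(0, 250e-6, by = px)
  rest <- filament_path(-W / 2 + s, rep(0, length(s)), s = s, height = 0,
                        pixel_scale = px)
  a <- 0.3 * pi / 180
  defl <- filament_path(-W / 2 + cos(a) * s, sin(a) * s, s = s, height = 0,
                        pixel_scale = px)
  expr <- deflection_experiment(rest, defl, env, radius = 2.2e-6)
  fit <- suppressWarnings(fit_filament_stiffness(expr))
  expect_equal(fit$alpha * 180 / pi, 0.3, tolerance = 0.15)
  # with the deflection absorbed by rotation, beta diverges (or is many
  # orders of magnitude above any physical filament stiffness)
  expect_true(!is.finite(fit$beta) || fit$beta > 1e-13)
})

test_that("predicted tip deflection grows with flow speed at fixed stiffness", {
  tips <- vapply(c(0.5, 1, 1.5, 2, 2.59) * 1e-3, function(U0) {
    syn <- suppressWarnings(gen_deflection_experiment(
      5e-17, 0, test_flow_env(U0 = U0), noise = 0, seed = 1))
    syn$truth$tip_deflection
  }, 0)
  expect_true(all(diff(tips) > 0))
})

test_that("per-point stiffness profiles behave as diagnostics", {
  env <- test_flow_env(U0 = 1e-3)
  syn <- gen_deflection_experiment(5e-17, 0, env, noise = 0, seed = 2)
  fit <- fit_filament_stiffness(syn$experiment)
  # noiseless self-consistent data: constant profile, negligible spread
  expect_equal(fit$beta_mean, fit$beta, tolerance = 1e-3)
  expect_lt(fit$beta_sd / fit$beta_mean, 1e-3)
  # moderate pixel noise: spread stays bounded for large tip deflections
  syn_n <- gen_deflection_experiment(5e-17, 0, env, noise = 0.5, seed = 4)
  fit_n <- fit_filament_stiffness(syn_n$experiment)
  expect_gt(fit_n$profile$delta_obs[nrow(fit_n$profile)],
            20 * syn_n$experiment$pixel_scale)
  expect_lt(fit_n$beta_sd / fit_n$beta_mean, 0.25)
  # a stiffness step along the filament shows up in the profile direction
  W <- env$geometry$width; px <- 0.5e-6
  s <- seq(0, 250e-6, by = px)
  xs <- -W / 2 + s
  rest <- filament_path(xs, rep(0, length(s)), s = s, height = 0,
                        pixel_scale = px)
  u <- channel_velocity(xs, rep(0, length(s)), env)
  w <- drag_coefficient(u, 2.2e-6, env$fluid, warn = FALSE)$xi * u
  # piecewise-stiffness beam oracle: integrate M'' = -w from the free end,
  # then delta'' = -M / beta(s) from the clamp
  beta_s <- ifelse(s < 125e-6, 5e-17, 1e-16)
  t1 <- pracma::cumtrapz(s, w); m1 <- t1 - t1[length(t1)]
  t2 <- pracma::cumtrapz(s, as.numeric(m1)); M <- -(t2 - t2[length(t2)])
  dd <- as.numeric(-M) / beta_s
  d1 <- pracma::cumtrapz(s, dd); d0 <- as.numeric(pracma::cumtrapz(s, as.numeric(d1)))
  defl <- filament_path(xs, d0, s = s, height = 0, pixel_scale = px)
  expr <- deflection_experiment(rest, defl, env, radius = 2.2e-6)
  fit_step <- fit_filament_stiffness(expr, allow_rotation = FALSE)
  prof <- fit_step$profile
  keep <- !is.na(prof$beta_local)
  first_half <- prof$beta_local[keep & prof$s < 125e-6]
  second_half <- prof$beta_local[keep & prof$s >= 125e-6]
  # the soft near-clamp half bends more than a uniform beam would,
  # depressing its apparent local stiffness relative to the stiff half
  expect_lt(mean(first_half), mean(second_half))
  # pointwise_stiffness honours a caller-supplied noise floor
  pw <- pointwise_stiffness(fit_n, noise_floor = 5 * px)
  expect_true(all(pw$profile$beta_local > 0))
  expect_error(pointwise_stiffness(fit_n, noise_floor = 1), "no-signal")
})

test_that("strand and species aggregation use the documented weighting", {
  # hand-computed inverse-variance weights
  ag <- aggregate_strand(data.frame(beta = c(4, 8), beta_sd = c(1, 2)))
  expect_equal(ag$beta, 4.8)
  # single fit passes through unchanged
  ag1 <- aggregate_strand(data.frame(beta = 5, beta_sd = 2))
  expect_equal(ag1$beta, 5); expect_equal(ag1$n, 1L)
  # identical fits: mean unchanged, uncertainty shrinks as 1/sqrt(n)
  agi <- aggregate_strand(data.frame(beta = c(5, 5, 5, 5),
                                     beta_sd = c(2, 2, 2, 2)))
  expect_equal(agi$beta, 5)
  expect_equal(agi$se, 2 / sqrt(4))
  expect_warning(
    ag0 <- aggregate_strand(data.frame(beta = c(4, 8), beta_sd = c(0, 2))),
    "unweighted")
  expect_equal(ag0$beta, 6)
  sp <- aggregate_species(c(4e-17, 5e-17, 6e-17))
  expect_equal(sp$beta, 5e-17); expect_equal(sp$n, 3L)
  expect_equal(sp$sd, sd(c(4e-17, 5e-17, 6e-17)))
})

test_that("degenerate experiments raise no-signal errors", {
  env <- test_flow_env(U0 = 1e-3)
  W <- env$geometry$width; px <- 0.5e-6
  s <- seq(0, 250e-6, by = px)
  rest <- filament_path(-W / 2 + s, rep(0, length(s)), s = s, height = 0,
                        pixel_scale = px)
  expr <- deflection_experiment(rest, rest, env, radius = 2.2e-6)
  expect_error(fit_filament_stiffness(expr), "no-signal")
})
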