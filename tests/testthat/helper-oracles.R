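# Independent numerical oracles used to validate the package's closed-form
# and series implementations.

# Finite-difference solution of the duct Poisson problem  lap(u) = -1  with
# no-slip walls, by eigendecomposition of the 1-D second-difference
# operators. Returns the velocity field normalized to unit cross-sectional
# mean (trapezoid quadrature) and the permeability (the raw mean, since
# U0 = k G / mu with G/mu = 1 here).
fd_duct_flow <- function(W, H, n = 201L) {
  m <- n - 2L
  hx <- W / (n - 1L); hz <- H / (n - 1L)
  d2 <- function(m, h) {
    A <- diag(-2, m)
    A[cbind(1:(m - 1L), 2:m)] <- 1
    A[cbind(2:m, 1:(m - 1L))] <- 1
    A / h^2
  }
  ea <- eigen(d2(m, hx), symmetric = TRUE)
  eb <- eigen(d2(m, hz), symmetric = TRUE)
  G <- crossprod(ea$vectors, matrix(-1, m, m)) %*% eb$vectors
  L <- outer(ea$values, eb$values, "+")
  U <- ea$vectors %*% (G / L) %*% t(eb$vectors)
  Uf <- matrix(0, n, n)
  Uf[2:(n - 1L), 2:(n - 1L)] <- U
  wq <- rep(1, n); wq[c(1L, n)] <- 0.5
  ubar <- sum(outer(wq, wq) * Uf) / sum(outer(wq, wq))
  list(x = seq(-W / 2, W / 2, length.out = n),
       z = seq(-H / 2, H / 2, length.out = n),
       u_over_U0 = Uf / ubar,
       k = ubar)
}

# Geometric (orthogonal-distance) least-squares circle fit: minimizes the
# sum of squared radial residuals directly with a general-purpose
# optimizer, initialized from the circumcircle of three spread points.
# Deliberately shares no code with the algebraic Pratt fit.
geometric_circle_fit <- function(x, y) {
  circum <- function(p1, p2, p3) {
    ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]
    cx <- p3[1]; cy <- p3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-300) return(c(mean(c(ax, bx, cx)), mean(c(ay, by, cy))))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy)
  }
  n <- length(x)
  i <- c(1L, ceiling(n / 2), n)
  ctr <- circum(c(x[i[1]], y[i[1]]), c(x[i[2]], y[i[2]]), c(x[i[3]], y[i[3]]))
  r0 <- mean(sqrt((x - ctr[1])^2 + (y - ctr[2])^2))
  sc <- max(r0, 1e-12)
  obj <- function(p) {
    sum((sqrt((x - p[1] * sc)^2 + (y - p[2] * sc)^2) - p[3] * sc)^2)
  }
  fit <- optim(c(ctr[1], ctr[2], r0) / sc, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(center = fit$par[1:2] * sc, radius = fit$par[3] * sc)
}

# Closed-form cantilever deflections (clamped at s = 0, free at s = L).
uniform_load_deflection <- function(s, w, L, beta) {
  w * s^2 * (6 * L^2 - 4 * L * s + s^2) / (24 * beta)
}
# triangular load w(s) = w0 (1 - s/L), maximum at the clamp
triangular_load_deflection <- function(s, w0, L, beta) {
  w0 / beta * (s^4 / 24 - s^5 / (120 * L) - L * s^3 / 12 + L^2 * s^2 / 12)
}

# default flow condition used across the stiffness tests
test_flow_env <- function(U0 = 1e-3, H = 134e-6) {
  flow_environment(channel_geometry(300e-6, H), mean_speed = U0)
}
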