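# Shared builders for the test suite.

ref_geometry <- function(...) geometry_box(0.5, 0.1, 0.1, ...)
ref_params <- function() poro_params(lambda_e = 0.5, mu_e = 0.25, k = 1)

# 1D coupled problem with the reference circuit
make_problem_1d <- function(variant = "ipc", nx = 40, pbar = NULL,
                            forcing = forcing_data(), R = 1, k = 1) {
  geom <- ref_geometry()
  params <- poro_params(0.5, 0.25, k)
  disc <- biot_discretization(mesh_interval(geom, nx), params, forcing)
  circ <- example_circuit(C = 0.1, pbar = pbar)
  biot0d_problem(disc, circ, coupling_spec(variant, R, 0.1, geom$m_sigma))
}

# unforced problem with nonzero initial displacement and circuit state
make_unforced_1d <- function(variant = "ipc", nx = 40) {
  u0 <- function(x) matrix(0.05 * sin(pi * x[, 1] / 0.5) * (0.5 - x[, 1]),
                           ncol = 1)
  make_problem_1d(variant, nx,
                  forcing = forcing_data(u0 = u0, y0 = c(0.3, -0.2, 0.1)))
}

# manufactured solution on the unit cube, all faces drained & clamped:
# u* = cvec * s(x) * t,  p* = s(x) * (1 + t),
# s = sin(pi x) sin(pi (y + 1/2)) sin(pi (z + 1/2))
mms <- local({
  cvec <- c(1, 2, -1) * 0.1
  fns <- list(function(v) sin(pi * v),
              function(v) sin(pi * (v + 0.5)),
              function(v) sin(pi * (v + 0.5)))
  gns <- list(function(v) pi * cos(pi * v),
              function(v) pi * cos(pi * (v + 0.5)),
              function(v) pi * cos(pi * (v + 0.5)))
  s <- function(x) fns[[1]](x[, 1]) * fns[[2]](x[, 2]) * fns[[3]](x[, 3])
  ds <- function(x, i) {
    out <- rep(1, nrow(x))
    for (j in 1:3) out <- out * (if (j == i) gns[[j]](x[, j]) else fns[[j]](x[, j]))
    out
  }
  d2s <- function(x, i, j) {
    if (i == j) return(-pi^2 * s(x))
    out <- rep(1, nrow(x))
    for (l in 1:3) {
      out <- out * (if (l == i || l == j) gns[[l]](x[, l]) else fns[[l]](x[, l]))
    }
    out
  }
  list(cvec = cvec, s = s, ds = ds, d2s = d2s,
       geometry = geometry_box(1, 1, 1, faces = list(
         xmin = "gammaDp", xmax = "gammaDp", ymin = "gammaDp",
         ymax = "gammaDp", zmin = "gammaDp", zmax = "gammaDp")),
       params = poro_params(1, 1, 0.5))
})

mms_forcing <- function() {
  lam <- mms$params$lambda_e; mu <- mms$params$mu_e; k <- mms$params$k
  Ffun <- function(x, t) {
    out <- matrix(0, nrow(x), 3)
    for (jj in 1:3) {
      graddiv <- rowSums(vapply(1:3, function(i) mms$cvec[i] * mms$d2s(x, jj, i),
                                numeric(nrow(x))))
      out[, jj] <- t * (mu * 3 * pi^2 * mms$cvec[jj] * mms$s(x) -
                          (lam + mu) * graddiv) + (1 + t) * mms$ds(x, jj)
    }
    out
  }
  Sfun <- function(x, t) {
    rowSums(vapply(1:3, function(i) mms$cvec[i] * mms$ds(x, i),
                   numeric(nrow(x)))) + k * 3 * pi^2 * mms$s(x) * (1 + t)
  }
  forcing_data(F = Ffun, S = Sfun)
}

mms_errors <- function(n, type, dt = 0.1, t_end = 0.2) {
  disc <- biot_discretization(mesh_box(mms$geometry, n, type), mms$params,
                              mms_forcing())
  tr <- run_operator_splitting(biot0d_problem(disc), dt = dt, t_end = t_end)
  tf <- tr$times[length(tr$times)]
  nod <- disc$mesh$nodes
  uex <- as.vector(outer(mms$s(nod), mms$cvec) * tf)
  pex <- mms$s(nod) * (1 + tf)
  du <- tr$U[, ncol(tr$U)] - uex
  dp <- tr$Pfield[, ncol(tr$Pfield)] - pex
  l2u <- sqrt(sum(vapply(1:3, function(c_) {
    v <- du[(c_ - 1) * disc$N + seq_len(disc$N)]
    as.numeric(Matrix::crossprod(v, disc$Mp %*% v))
  }, 0)))
  l2p <- sqrt(as.numeric(Matrix::crossprod(dp, disc$Mp %*% dp)))
  c(u = l2u, p = l2p)
}

# independent stationary oracle: solve the continuous steady coupled system
# (constant strain/pressure column + circuit balance) as a small dense
# linear system in (strain, p, pi, pi1, Q1, P, Q).
steady_brute_force <- function(params, g, pbar, geometry, R = 1, Rbar = 1,
                               R1 = 1, C1 = 0.1, L1 = 1, C = 0.1) {
  ab <- geometry$a * geometry$b
  # unknowns: e, p, pi, pi1, Q1, P, Q
  A <- matrix(0, 7, 7); b <- numeric(7)
  A[1, ] <- c(params$H_A, -1, 0, 0, 0, 0, 0); b[1] <- g      # T(0) = g
  A[2, ] <- c(0, 1, -1, 0, 0, 0, 0)                          # p = pi (v = 0)
  A[3, ] <- c(0, 0, 0, 0, -1 / C, 0, 1 / C)                  # d pi/dt = 0
  A[4, ] <- c(0, 0, 0, -1 / (Rbar * C1), 1 / C1, 0, 0)       # d pi1/dt = 0
  b[4] <- -pbar / (Rbar * C1)
  A[5, ] <- c(0, 0, 1 / L1, -1 / L1, -R1 / L1, 0, 0)         # d Q1/dt = 0
  A[6, ] <- c(0, 0, 1 / R, 0, 0, -1 / R, 1)                  # Q - (P-pi)/R = 0
  A[7, ] <- c(0, 1, 0, 0, 0, -1, 0)                          # P = p (mean)
  x <- solve(A, b)
  list(strain = x[1], p = x[2], pi = x[3], pi1 = x[4], Q1 = x[5],
       P = x[6], Q = x[7])
}
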