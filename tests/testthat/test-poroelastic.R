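# Biot solver: zero solutions, manufactured-solution convergence, field
# evaluation, mass budget, 1D/3D consistency.

test_that("homogeneous data give the zero solution", {
  disc <- biot_discretization(mesh_box(mms$geometry, 2, "hex"), mms$params)
  tr <- run_operator_splitting(biot0d_problem(disc), dt = 0.1, t_end = 0.3)
  expect_equal(max(abs(tr$U)), 0)
  expect_equal(max(abs(tr$Pfield)), 0)
  pb1 <- make_problem_1d("ipc", nx = 20)
  tr1 <- run_operator_splitting(pb1, dt = 0.1, t_end = 0.5)
  expect_equal(max(abs(tr1$U)), 0)
  expect_equal(max(abs(tr1$Y)), 0)
})

test_that("manufactured solution converges under mesh refinement", {
  eh1 <- mms_errors(3, "hex")
  eh2 <- mms_errors(6, "hex")
  # L2 rates approach 2; accept > 1.5 on this coarse pair
  expect_gt(log2(eh1["u"] / eh2["u"]), 1.5)
  expect_gt(log2(eh1["p"] / eh2["p"]), 1.5)
  et1 <- mms_errors(3, "tet")
  et2 <- mms_errors(6, "tet")
  expect_gt(log2(et1["u"] / et2["u"]), 1.0)
  expect_gt(log2(et1["p"] / et2["p"]), 1.2)
})

test_that("x-only data on the 3D box produce an exactly 1D solution", {
  pr <- preset_oned_conducive(scale = 0.1, variant = "ipc", n = c(6, 3, 3), t_end = 2)
  tr <- run_operator_splitting(pr$problem, dt = 0.02, t_end = 2)
  disc <- pr$problem$disc
  N <- disc$N
  ncol_ <- ncol(tr$U)
  uyz <- tr$U[N + seq_len(2 * N), ncol_]
  expect_lt(max(abs(uyz)), 1e-10 * max(max(abs(tr$U[, ncol_])), 1e-30))
  # pressure constant on every x-plane
  xs <- disc$mesh$nodes[, 1]
  pf <- tr$Pfield[, ncol_]
  for (xv in unique(xs)) {
    expect_lt(diff(range(pf[xs == xv])), 1e-12 * max(abs(pf), 1e-30))
  }
})

test_that("3D solver matches the 1D solver on 1D-conducive data", {
  pr <- preset_oned_conducive(scale = 0.1, variant = "ipc", n = c(10, 3, 3),
                      nx1d = 10, t_end = 2)
  tr3 <- run_operator_splitting(pr$problem, dt = 0.02, t_end = 2)
  tr1 <- run_operator_splitting(pr$problem_1d, dt = 0.02, t_end = 2)
  # same axial resolution: nodal profiles agree to solver precision
  disc3 <- pr$problem$disc
  x3 <- disc3$mesh$nodes[, 1]
  x1 <- pr$problem_1d$disc$mesh$nodes[, 1]
  n <- length(tr3$times)
  p3 <- tr3$Pfield[order(x3), n][!duplicated(sort(x3))]
  p1 <- tr1$Pfield[order(x1), n]
  expect_equal(p3, p1, tolerance = 1e-9)
  expect_equal(tr3$Y[, n], tr1$Y[, n], tolerance = 1e-9)
})

test_that("stress and velocity evaluation match closed forms", {
  geom <- geometry_box(1, 1, 1)
  params <- poro_params(1, 1, 1)
  disc <- biot_discretization(mesh_box(geom, 2, "hex"), params)
  N <- disc$N
  # p = x (linear), k = 1  ->  v = (-1, 0, 0) everywhere
  p <- disc$mesh$nodes[, 1]
  v <- eval_velocity(disc, p)
  expect_equal(v, matrix(rep(c(-1, 0, 0), each = nrow(v)), ncol = 3),
               tolerance = 1e-13)
  # u = 0, p = p0  ->  T = -p0 I
  Tarr <- eval_stress(disc, numeric(3 * N), rep(2.5, N))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(Tarr[, i, j], rep(if (i == j) -2.5 else 0, dim(Tarr)[1]),
                 tolerance = 1e-13)
  }
  # 1D: H_A = 1, du/dx = 2, p = 1 -> T = 1
  d1 <- biot_discretization(mesh_interval(geometry_box(0.5, 0.1, 0.1), 4),
                            poro_params(0.5, 0.25, 1))
  x <- d1$mesh$nodes[, 1]
  expect_equal(eval_stress(d1, 2 * x, rep(1, d1$N)),
               rep(1, 4), tolerance = 1e-13)
})

test_that("discrete mass budget closes without sources or coupling", {
  # impermeable/natural pressure boundaries everywhere, traction drive
  geom <- geometry_box(1, 1, 1, faces = list(
    xmin = "gammaN", xmax = "gammaDv", ymin = "gammaN", ymax = "gammaN",
    zmin = "gammaN", zmax = "gammaN"))
  gfun <- function(x, t) {
    out <- matrix(0, nrow(x), 3)
    out[abs(x[, 1]) < 1e-12, 1] <- 0.1 * t
    out
  }
  disc <- biot_discretization(mesh_box(geom, 2, "hex"),
                              poro_params(1, 1, 1), forcing_data(g = gfun))
  tr <- run_operator_splitting(biot0d_problem(disc), dt = 0.05, t_end = 0.25)
  # with v.n = 0 on the whole boundary, d/dt int div u must vanish
  for (n in 2:ncol(tr$U)) {
    div_new <- sum(disc$D %*% tr$U[, n])
    div_old <- sum(disc$D %*% tr$U[, n - 1])
    expect_lt(abs(div_new - div_old) / tr$dt,
              1e-10 * max(1, abs(div_new)))
  }
})

test_that("1D transient converges in time to the steady oracle", {
  ps <- preset_steady1d(g = 0.2, pbar = 1, variant = "ipc", nx = 30)
  tr <- run_operator_splitting(ps$problem, dt = 0.05, t_end = 60)
  n <- length(tr$times)
  orc <- ps$oracle
  x <- ps$problem$disc$mesh$nodes[, 1]
  expect_lt(max(abs(tr$Pfield[, n] - orc$p_inf)), 1e-8)
  expect_lt(max(abs(tr$U[, n] - orc$u_inf(x))), 1e-8)
  expect_lt(max(abs(tr$Y[, n] - c(orc$pi_inf, orc$pi1_inf, orc$Q1_inf))), 1e-8)
  # geometric approach: error at t=30 already far below error at t=10
  i10 <- which.min(abs(tr$times - 10))
  i30 <- which.min(abs(tr$times - 30))
  e10 <- max(abs(tr$Pfield[, i10] - orc$p_inf))
  e30 <- max(abs(tr$Pfield[, i30] - orc$p_inf))
  expect_lt(e30, e10 * 1e-2)
})
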