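# Interface conditions: Robin elimination coefficients, PPC flatness,
# 1D variant equivalence, Ohm residual, interface statistics.

test_that("IPC Robin coefficients match the eliminated Backward Euler form", {
  co <- ipc_robin_coefficients(R = 1, C = 0.1, dt = 0.02, pi_n = 3, K = 0.01)
  expect_equal(co$coef_mean, 1 / 6)
  expect_equal(co$rhs_factor, 5 / 6)
  expect_equal(co$rhs, -5 / 6 * 3)
  expect_equal(co$coef_flux, 0.01)
  # dt -> 0: condition tends to K v.n = p - pi_n
  co0 <- ipc_robin_coefficients(R = 1, C = 0.1, dt = 1e-12, pi_n = 2)
  expect_lt(co0$coef_mean, 1e-10)
  expect_equal(co0$rhs, -2, tolerance = 1e-10)
  # fixed point of the pi update
  expect_equal(co$pi_update(3), 3)
  expect_error(ipc_robin_coefficients(-1, 0.1, 0.02), "positive")
})

test_that("PPC enforces an exactly flat interface pressure", {
  pr <- preset_infiltration(variant = "ppc", n = c(6, 4, 4), t_end = 1)
  tr <- run_operator_splitting(pr$problem, dt = 0.02, t_end = 1)
  disc <- pr$problem$disc
  n <- length(tr$times)
  trc <- tr$Pfield[disc$sigma$pnodes, n]
  expect_lt(max(trc) - min(trc), 1e-10 * max(abs(tr$Pfield[, n])))
  # and the trace value is the reported scalar P
  expect_equal(unique(round(trc, 14)), round(tr$P[n - 1], 14))
})

test_that("PPC and IPC coincide on 1D problems", {
  pb_i <- make_problem_1d("ipc", nx = 40,
                          pbar = function(t) 0.1 * sin(2 * pi * t / 5))
  pb_p <- make_problem_1d("ppc", nx = 40,
                          pbar = function(t) 0.1 * sin(2 * pi * t / 5))
  tri <- run_operator_splitting(pb_i, dt = 0.02, t_end = 5)
  trp <- run_operator_splitting(pb_p, dt = 0.02, t_end = 5)
  scl <- max(abs(tri$Y))
  expect_lt(max(abs(tri$Y - trp$Y)), 1e-10 * scl)
  expect_lt(max(abs(tri$Pfield - trp$Pfield)), 1e-10 * scl)
  expect_lt(max(abs(tri$Q - trp$Q)), 1e-10 * max(abs(tri$Q)))
})

test_that("hydraulic Ohm law holds at every accepted step", {
  for (v in c("ipc", "ppc")) {
    pb <- make_problem_1d(v, nx = 30,
                          pbar = function(t) 0.2 * sin(t))
    tr <- run_operator_splitting(pb, dt = 0.05, t_end = 2)
    resid <- abs(tr$Q - (tr$P - tr$pi) / pb$coupling$R)
    expect_true(all(resid <= 1e-10 * pmax(1, abs(tr$Q))))
  }
})

test_that("interface statistics evaluate quadrature exactly", {
  geom <- geometry_box(0.5, 0.1, 0.1)
  disc <- biot_discretization(mesh_box(geom, c(4, 3, 3), "hex"), ref_params())
  N <- disc$N
  # p constant on Sigma
  p <- rep(3, N)
  st <- interface_statistics(disc, p)
  expect_equal(st$P_mean, 3, tolerance = 1e-13)
  expect_equal(st$p_max - st$p_min, 0)
  # p linear in x: p = -2x/k gives v = (2,0,0), Q = 2 * 0.01
  p2 <- -2 * disc$mesh$nodes[, 1] / disc$params$k
  st2 <- interface_statistics(disc, p2)
  expect_equal(st2$Q, 0.02, tolerance = 1e-12)
  # zero-mean y-linear trace integrates to zero mean
  p3 <- disc$mesh$nodes[, 2]
  st3 <- interface_statistics(disc, p3)
  expect_lt(abs(st3$P_mean), 1e-15)
})

test_that("IPC reduces to flat interface pressure on 1D-conducive 3D data", {
  pr <- preset_oned_conducive(scale = 0.1, variant = "ipc", n = c(6, 3, 3), t_end = 1)
  tr <- run_operator_splitting(pr$problem, dt = 0.02, t_end = 1)
  disc <- pr$problem$disc
  n <- length(tr$times)
  trc <- tr$Pfield[disc$sigma$pnodes, n]
  expect_lt(max(trc) - min(trc), 1e-12 * max(abs(tr$Pfield), 1e-30))
})

test_that("interface u = 0 is enforced exactly for both variants", {
  for (v in c("ipc", "ppc")) {
    pr <- preset_infiltration(variant = v, n = c(5, 3, 3), t_end = 0.5)
    tr <- run_operator_splitting(pr$problem, dt = 0.05, t_end = 0.5)
    disc <- pr$problem$disc
    N <- disc$N
    sn <- disc$sigma$pnodes
    idx <- c(sn, N + sn, 2 * N + sn)
    expect_equal(max(abs(tr$U[idx, ])), 0)
  }
})

test_that("missing interface tag is reported", {
  geom <- geometry_box(1, 1, 1, faces = list(xmax = "gammaN"))
  disc <- biot_discretization(mesh_box(geom, 2, "hex"), ref_params())
  expect_error(
    biot0d_problem(disc, example_circuit(),
                   coupling_spec("ipc", 1, 0.1, 1)),
    "sigma")
})
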