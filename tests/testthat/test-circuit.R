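# Lumped circuit: state-space assembly, energies, passivity, exact solution
# and the Backward Euler stepper.

test_that("example circuit reproduces the reference state matrix", {
  m <- example_circuit(Rbar = 1, R1 = 1, C = 0.1, C1 = 0.1, L1 = 1)
  expect_equal(m$A, rbind(c(0, 0, -10), c(0, -10, 10), c(1, -1, -1)))
  expect_equal(m$U, c(0.1, 0.1, 1))

  m2 <- example_circuit(Rbar = 1, R1 = 3, C = 1, C1 = 1, L1 = 2)
  expect_equal(m2$A, rbind(c(0, 0, -1), c(0, -1, 1), c(0.5, -0.5, -1.5)))

  # B = -UA holds entrywise for arbitrary valid parameters
  set.seed(7)
  for (i in 1:5) {
    v <- runif(5, 0.1, 3)
    mm <- example_circuit(v[1], v[2], v[3], v[4], v[5])
    expect_equal(mm$B, -diag(mm$U) %*% mm$A, tolerance = 1e-14,
                 ignore_attr = TRUE)
  }

  expect_error(example_circuit(Rbar = -1), "positive")
  expect_error(circuit_model(diag(2), c(1, -1)), "positive")
})

test_that("circuit energy and dissipation quadratic forms", {
  m <- example_circuit(Rbar = 1, R1 = 1, C = 0.1, C1 = 0.1, L1 = 1)
  expect_identical(circuit_energy(m, c(0, 0, 0)), 0)
  expect_equal(circuit_energy(m, c(1, 0, 0)), 0.05)
  expect_equal(circuit_energy(m, c(0, 2, 3)), 4.7)
  # the connecting-node pressure is lossless; Pi1 dissipates through Rbar
  expect_equal(circuit_dissipation(m, c(5, 0, 0)), 0)
  expect_equal(circuit_dissipation(m, c(0, 1, 0)), 1)
  expect_identical(circuit_dissipation(m, c(0, 0, 0)), 0)
  expect_error(circuit_energy(m, c(1, 2)), "mismatch")
})

test_that("passivity: y'By >= 0 for random states and parameters", {
  set.seed(11)
  for (rep in 1:20) {
    v <- runif(5, 0.05, 5)
    m <- example_circuit(v[1], v[2], v[3], v[4], v[5])
    Y <- matrix(rnorm(3 * 50), 50, 3)
    q <- rowSums((Y %*% m$B) * Y)
    expect_true(all(q >= -1e-12 * max(1, max(abs(m$B)))))
  }
})

test_that("exact solver handles degenerate and stationary cases", {
  # A = 0: y(t) = y0 + t * s
  m0 <- circuit_model(matrix(0, 2, 2), c(1, 1),
                      s = function(t) c(2, -1), C_conn = 1)
  ex <- solve_circuit_exact(m0, NULL, c(1, 1), c(0, 0.5, 1.5), micro_n = 100)
  expect_equal(ex$y[2, ], c(1, 1) + 0.5 * c(2, -1), tolerance = 1e-12)
  expect_equal(ex$y[3, ], c(1, 1) + 1.5 * c(2, -1), tolerance = 1e-12)

  # zero data stays zero
  m <- example_circuit()
  ex0 <- solve_circuit_exact(m, NULL, c(0, 0, 0), c(0, 1), micro_n = 50)
  expect_equal(max(abs(ex0$y)), 0)

  # constant source, long time: stationary point of Ay + s = 0 is (1, 1, 0)
  mc <- example_circuit(pbar = function(t) rep(1, length(t)))
  exs <- solve_circuit_exact(mc, NULL, c(0, 0, 0), c(0, 50), micro_n = 2000)
  expect_equal(exs$y[2, ], c(1, 1, 0), tolerance = 1e-10)
})

test_that("Backward Euler stepper is exact for A = 0 and first order overall", {
  m0 <- circuit_model(matrix(0, 2, 2), c(1, 1), C_conn = 1)
  expect_equal(step_circuit_be(m0, c(3, -2), Q = 0, dt = 0.7, t_next = 1),
               c(3, -2))

  m <- example_circuit(pbar = function(t) sin(t))
  Qf <- function(t) 0.1 * cos(2 * t)
  y0 <- c(0.2, -0.1, 0.05)
  Tend <- 2
  yref <- solve_circuit_exact(m, Qf, y0, c(0, Tend), micro_n = 1e4)$y[2, ]
  errs <- vapply(100 * 2^(0:4), function(nsteps) {
    dt <- Tend / nsteps
    y <- y0
    for (n in seq_len(nsteps)) {
      y <- step_circuit_be(m, y, Q = Qf(n * dt), dt = dt, t_next = n * dt)
    }
    sqrt(sum((y - yref)^2))
  }, 0)
  ratios <- errs[-5] / errs[-1]
  expect_true(all(abs(ratios - 2) < 0.2))
})

test_that("unforced Backward Euler steps never increase circuit energy", {
  m <- example_circuit()
  set.seed(3)
  for (dt in c(1e-3, 0.1, 10)) {
    y <- rnorm(3)
    for (n in 1:20) {
      y1 <- step_circuit_be(m, y, Q = 0, dt = dt, t_next = n * dt)
      expect_lte(circuit_energy(m, y1),
                 circuit_energy(m, y) * (1 + 1e-12) + 1e-15)
      y <- y1
    }
  }
})

test_that("energy balance holds along forced exact solutions", {
  m <- example_circuit(pbar = function(t) 0.5 + 0.3 * sin(t))
  Qf <- function(t) 0.2 * cos(1.3 * t)
  y0 <- c(0.1, 0.2, -0.1)
  h <- 1e-3
  tpts <- c(1, 2.5)
  grid <- sort(c(0, tpts - h, tpts, tpts + h))
  sol <- solve_circuit_exact(m, Qf, y0, grid, micro_n = 4e4)
  for (tp in tpts) {
    i <- match(tp, grid)
    Em <- circuit_energy(m, sol$y[i - 1, ])
    Ep <- circuit_energy(m, sol$y[i + 1, ])
    dE <- (Ep - Em) / (2 * h)
    y <- sol$y[i, ]
    bal <- dE + circuit_dissipation(m, y) - sum(m$U * y * m$s(tp)) -
      y[1] * Qf(tp)
    scale <- max(abs(dE), circuit_dissipation(m, y), 1e-3)
    expect_lt(abs(bal) / scale, 1e-6)
  }
})
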