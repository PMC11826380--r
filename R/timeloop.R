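# Time integration drivers: energy-stable operator splitting and the
# partitioned PQP fixed-point iteration.

#' Coupled poroelastic--circuit problem
#'
#' Bundles a spatial discretization, a circuit model and a coupling
#' specification into one simulation-ready object, and checks their mutual
#' consistency: the connection capacitance of the coupling must equal the
#' connecting-node capacitance of the circuit, and the interface measure
#' must match the mesh's.
#'
#' @param disc a [biot_discretization()].
#' @param circuit a [circuit_model()]; `NULL` for an uncoupled Biot run.
#' @param coupling a [coupling_spec()]; `NULL` for an uncoupled run.
#' @return Object of class `biot0d_problem`.
#' @export
biot0d_problem <- function(disc, circuit = NULL, coupling = NULL) {
  stopifnot(inherits(disc, "biot_disc"))
  if (is.null(circuit) != is.null(coupling)) {
    stop("supply both 'circuit' and 'coupling', or neither")
  }
  if (!is.null(coupling)) {
    stopifnot(inherits(circuit, "circuit_model"),
              inherits(coupling, "coupling_spec"))
    if (is.null(disc$sigma)) {
      stop("mesh has no face labelled 'sigma'; cannot couple")
    }
    if (abs(coupling$C - circuit$C_conn) > 1e-12 * coupling$C) {
      stop("coupling capacitance C (", coupling$C, ") must equal the ",
           "circuit connection capacitance (", circuit$C_conn, ")")
    }
    if (abs(coupling$m_sigma - disc$sigma$m_sigma) >
          1e-8 * coupling$m_sigma) {
      stop("coupling m_sigma (", coupling$m_sigma, ") does not match the ",
           "mesh interface measure (", disc$sigma$m_sigma, ")")
    }
  }
  structure(list(disc = disc, circuit = circuit, coupling = coupling),
            class = "biot0d_problem")
}

#' @export
print.biot0d_problem <- function(x, ...) {
  cat("<biot0d_problem>", if (is.null(x$coupling)) "uncoupled" else
    toupper(x$coupling$variant), "\n")
  print(x$disc)
  if (!is.null(x$circuit)) print(x$circuit)
  invisible(x)
}

initial_state <- function(problem) {
  disc <- problem$disc
  frc <- disc$forcing
  N <- disc$N
  u0 <- numeric(disc$nu)
  if (!is.null(frc$u0)) {
    uv <- matrix(frc$u0(disc$mesh$nodes), ncol = disc$ncomp)
    for (c_ in seq_len(disc$ncomp)) u0[(c_ - 1) * N + seq_len(N)] <- uv[, c_]
  }
  # enforce essential conditions on the initial displacement
  fixed <- setdiff(seq_len(disc$ndof), disc$free)
  u0[intersect(fixed, seq_len(disc$nu))] <- 0
  y0 <- frc$y0
  if (is.null(y0)) {
    y0 <- if (is.null(problem$circuit)) numeric(0) else numeric(problem$circuit$d)
  }
  list(u0 = u0, y0 = y0)
}

#' Run the operator-splitting time integration
#'
#' Advances the coupled problem with the two-substep splitting: Step 1
#' solves the Biot system together with the connection (the connecting-node
#' ODE `C dpi/dt = Q`) implicitly by Backward Euler, using the variant's
#' interface treatment; Step 2 advances the full internal circuit ODE
#' `dy/dt = A y + s(t)` by Backward Euler from the half-updated state. The
#' substeps communicate only through initial conditions (no sub-iterations),
#' and the scheme is unconditionally energy stable in the time step. The
#' ordering of the substeps can be reversed (`order = "circuit_first"`);
#' both orderings are stable and agree to first order in `dt`.
#'
#' @param problem a [biot0d_problem()].
#' @param dt time step (s).
#' @param t_end final time (s); the number of steps is `round(t_end/dt)`.
#' @param order `"biot_first"` (default) or `"circuit_first"`.
#' @param n_steps optional explicit number of steps (overrides `t_end`).
#' @return Object of class `biot0d_trajectory`: times, displacement and
#'   pressure snapshots (columns), circuit states `Y`, interface series
#'   `P`, `Q`, `pi`, and the half-step circuit states needed for the energy
#'   audit.
#' @export
run_operator_splitting <- function(problem, dt, t_end,
                                   order = c("biot_first", "circuit_first"),
                                   n_steps = NULL) {
  stopifnot(inherits(problem, "biot0d_problem"))
  order <- match.arg(order)
  disc <- problem$disc
  coupled <- !is.null(problem$coupling)
  if (is.null(n_steps)) n_steps <- max(1L, round(t_end / dt))
  times <- dt * (0:n_steps)
  st <- initial_state(problem)
  step1 <- build_step1(disc, problem$coupling, dt)

  U <- matrix(0, disc$nu, n_steps + 1)
  Pf <- matrix(0, disc$np, n_steps + 1)
  U[, 1] <- st$u0
  d <- if (coupled) problem$circuit$d else 0
  Y <- matrix(0, max(d, 1), n_steps + 1)
  if (coupled) Y[, 1] <- st$y0
  Pser <- Qser <- pis <- pistar <- rep(NA_real_, n_steps)

  u <- st$u0
  y <- if (coupled) st$y0 else numeric(0)
  for (n in seq_len(n_steps)) {
    tn1 <- times[n + 1]
    if (coupled && order == "circuit_first") {
      y <- step_circuit_be(problem$circuit, y, Q = 0, dt = dt, t_next = tn1)
      pistar[n] <- y[1]
    }
    res <- step1$solve(tn1, u, if (coupled) y[1] else 0)
    u <- res$u
    if (coupled) {
      y_half <- y
      y_half[1] <- res$pi_new
      if (order == "biot_first") {
        y <- step_circuit_be(problem$circuit, y_half, Q = 0, dt = dt,
                             t_next = tn1)
      } else {
        y <- y_half
      }
      Y[, n + 1] <- y
      Pser[n] <- res$P; Qser[n] <- res$Q; pis[n] <- res$pi_new
    }
    U[, n + 1] <- u
    Pf[, n + 1] <- res$p
  }
  structure(list(problem = problem, scheme = "os", order = order,
                 variant = if (coupled) problem$coupling$variant else "none",
                 dt = dt, times = times, U = U, Pfield = Pf, Y = Y,
                 P = Pser, Q = Qser, pi = pis, pi_star = pistar),
            class = "biot0d_trajectory")
}

#' @export
print.biot0d_trajectory <- function(x, ...) {
  cat("<biot0d_trajectory>", x$scheme, toupper(x$variant), "-",
      length(x$times) - 1, "steps of dt =", x$dt, "s\n")
  if (!is.null(x$diagnostics)) {
    cat("  PQP: diverged =", isTRUE(x$diagnostics$diverged),
        "; max gamma2 =", suppressWarnings(max(x$diagnostics$gamma2,
                                               na.rm = TRUE)), "\n")
  }
  invisible(x)
}

#' Run the partitioned PQP fixed-point iteration
#'
#' Alternative driver that decouples the two models within each time step:
#' given an interface pressure iterate `P_j`, the Biot system is solved with
#' the Dirichlet condition `p = P_j` on the whole interface, the resulting
#' flow rate `Q_{j+1}` (variationally consistent interface reaction) drives
#' a Backward Euler circuit update, and the hydraulic Ohm law returns the
#' next iterate `P_{j+1} = pi_{j+1} + R Q_{j+1}`. The map is affine in
#' `P_j`; its empirical contraction factor
#' `gamma2_hat = |P_{j+2} - P_{j+1}| / |P_{j+1} - P_j|` is recorded per
#' step. The iteration is only conditionally convergent: the factor grows
#' as the time step shrinks, the connecting resistance grows, or the
#' permeability shrinks, and divergence manifests as iterate blow-up.
#' Non-convergence is reported in the diagnostics, not as an error.
#'
#' @param problem a coupled [biot0d_problem()].
#' @param dt,t_end time step and final time (s).
#' @param tol relative fixed-point tolerance on `P`.
#' @param max_iter maximum inner iterations per step.
#' @param guard overflow guard: iterates beyond this magnitude flag blow-up
#'   and abort the run.
#' @param n_steps optional explicit number of steps.
#' @return A `biot0d_trajectory` with a `diagnostics` list: per-step
#'   iteration counts, empirical contraction factors `gamma2`, `converged`
#'   flags, and a global `diverged` flag.
#' @export
run_pqp <- function(problem, dt, t_end, tol = 1e-10, max_iter = 100,
                    guard = 1e12, n_steps = NULL) {
  stopifnot(inherits(problem, "biot0d_problem"))
  if (is.null(problem$coupling)) stop("PQP needs a coupled problem")
  if (tol <= 0) stop("'tol' must be positive")
  disc <- problem$disc
  cpl <- problem$coupling
  circ <- problem$circuit
  if (is.null(n_steps)) n_steps <- max(1L, round(t_end / dt))
  times <- dt * (0:n_steps)
  st <- initial_state(problem)

  N <- disc$N; nu <- disc$nu
  Mfull <- rbind(
    cbind(disc$A_el, -Matrix::t(disc$D)),
    cbind(disc$D / dt, disc$Kp)
  )
  trace_p <- nu + disc$sigma$pnodes
  free2 <- setdiff(disc$free, trace_p)
  M22 <- Mfull[free2, free2]
  Mcol <- Mfull[free2, trace_p, drop = FALSE]
  Mtr <- Mfull[trace_p, , drop = FALSE]
  fac <- Matrix::lu(methods::as(M22, "CsparseMatrix"))
  e1 <- c(1, numeric(circ$d - 1))

  U <- matrix(0, nu, n_steps + 1)
  Pf <- matrix(0, N, n_steps + 1)
  Y <- matrix(0, circ$d, n_steps + 1)
  U[, 1] <- st$u0
  Y[, 1] <- st$y0
  Pser <- Qser <- rep(NA_real_, n_steps)
  iters <- integer(n_steps)
  gam <- conv <- rep(NA_real_, n_steps)
  diverged <- FALSE

  u <- st$u0
  y <- st$y0
  P <- y[1]
  for (n in seq_len(n_steps)) {
    tn1 <- times[n + 1]
    lv <- load_vectors(disc, tn1)
    rhs <- numeric(disc$ndof)
    rhs[seq_len(nu)] <- lv$fu
    rhs[nu + seq_len(N)] <- as.numeric(disc$D %*% u) / dt + lv$fp
    hist <- numeric(0)
    ok <- FALSE
    for (j in seq_len(max_iter)) {
      # Biot solve with p = P on Sigma (full-trace Dirichlet)
      rr <- rhs[free2] - as.numeric(Mcol %*% rep(P, length(trace_p)))
      x2 <- Matrix::solve(fac, rr)
      xf <- numeric(disc$ndof)
      xf[free2] <- as.numeric(x2)
      xf[trace_p] <- P
      # variationally consistent interface flow rate
      Q <- sum(rhs[trace_p] - as.numeric(Mtr %*% xf))
      # circuit update driven by Q, then hydraulic Ohm law
      ynew <- step_circuit_be(circ, y, Q = Q, dt = dt, t_next = tn1)
      Pnew <- ynew[1] + cpl$R * Q
      hist <- c(hist, abs(Pnew - P))
      if (abs(Pnew) > guard) {
        diverged <- TRUE
        break
      }
      if (abs(Pnew - P) <= tol * max(1, abs(P))) {
        P <- Pnew
        u <- xf[seq_len(nu)]
        pvec <- xf[nu + seq_len(N)]
        y <- ynew
        ok <- TRUE
        iters[n] <- j
        break
      }
      P <- Pnew
      if (j == max_iter) iters[n] <- j
    }
    m <- length(hist)
    gam[n] <- if (m >= 2) hist[m] / hist[m - 1] else NA_real_
    conv[n] <- ok
    if (diverged) break
    if (!ok) next
    U[, n + 1] <- u
    Pf[, n + 1] <- pvec
    Y[, n + 1] <- y
    Pser[n] <- P
    Qser[n] <- (P - y[1]) / cpl$R
  }
  structure(list(problem = problem, scheme = "pqp", order = "pqp",
                 variant = cpl$variant, dt = dt, times = times,
                 U = U, Pfield = Pf, Y = Y, Yhalf = NULL,
                 P = Pser, Q = Qser, pi = Y[1, -1],
                 diagnostics = list(iterations = iters, gamma2 = gam,
                                    converged = conv, diverged = diverged)),
            class = "biot0d_trajectory")
}
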