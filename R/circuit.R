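#' Lumped hydraulic circuit model
#'
#' Represents the linear time-invariant state-space system
#' `dy/dt = A y + s(t) + b Q(t)` describing an RCL hydraulic network. The
#' state `y = (pi, Pi_1..Pi_nC, Q_1..Q_nL)` collects the connecting-node
#' pressure, the capacitor pressure differences and the inductor flow rates.
#' The input vector is `b = e1 / C`, with `C` the capacitance of the
#' connection to the poroelastic medium, so an inflow `Q` charges the
#' connecting node. The energy matrix `U = diag(C, C_1, ..., L_1, ...)`
#' defines the stored energy `y' U y / 2`, and `B = -U A` the dissipation
#' quadratic form `y' B y`.
#'
#' For a passive network the symmetric part of `B` must be positive
#' semidefinite; this is validated at construction. (Semidefiniteness, not
#' strict definiteness, is the property actually needed and the one that
#' holds for the bundled example network, whose dissipation vanishes on pure
#' connecting-node-pressure states.)
#'
#' @param A d x d state matrix (entries in 1/s).
#' @param U diagonal energy matrix: a length-d positive vector, or a d x d
#'   diagonal matrix of capacitances and inductances.
#' @param s source function `function(t)` returning the length-d source
#'   vector (pressure/flow sources); `NULL` means no sources.
#' @param C_conn capacitance of the connection (scale of the `b Q` input,
#'   `b = e1 / C_conn`). Defaults to `U[1]`, the connecting-node capacitance.
#' @param params optional named list of the physical element values the
#'   matrices were built from (kept for reporting).
#' @return An object of class `circuit_model` with elements `d`, `A`, `U`
#'   (vector of diagonal entries), `B`, `s`, `C_conn`, `params`.
#' @seealso [example_circuit()] for the bundled three-state network.
#' @export
circuit_model <- function(A, U, s = NULL, C_conn = NULL, params = list()) {
  A <- as.matrix(A)
  d <- nrow(A)
  if (ncol(A) != d) stop("'A' must be square")
  if (is.matrix(U)) {
    if (any(U[row(U) != col(U)] != 0)) stop("'U' must be diagonal")
    U <- diag(U)
  }
  U <- as.numeric(U)
  if (length(U) != d) stop("dimension mismatch between 'A' and 'U'")
  if (any(!is.finite(U)) || any(U <= 0)) {
    stop("'U' must have strictly positive diagonal entries")
  }
  if (is.null(C_conn)) C_conn <- U[1L]
  if (!is.numeric(C_conn) || C_conn <= 0) stop("'C_conn' must be positive")
  if (is.null(s)) s <- function(t) numeric(d)
  s0 <- s(0)
  if (length(s0) != d) stop("'s(t)' must return a length-d vector")
  B <- -U * A  # row-scaling: -diag(U) %*% A
  # passivity: symmetric part of B positive semidefinite, tol relative to |B|
  Bs <- (B + t(B)) / 2
  ev <- eigen(Bs, symmetric = TRUE, only.values = TRUE)$values
  scl <- max(1, max(abs(B)))
  if (min(ev) < -1e-12 * scl) {
    stop("circuit is not passive: symmetric part of B = -UA has a negative ",
         "eigenvalue (", format(min(ev)), ")")
  }
  structure(
    list(d = d, A = A, U = U, B = B, s = s, C_conn = C_conn, params = params),
    class = "circuit_model"
  )
}

#' @export
print.circuit_model <- function(x, ...) {
  cat("<circuit_model> d =", x$d, "states\n")
  cat("  U diag:", paste(signif(x$U, 4), collapse = ", "), "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Three-state example circuit (series Rbar-C1-L1/R1 network with connection)
#'
#' Builds the reference hydraulic network used throughout the package's test
#' problems: a pressure source `pbar(t)` behind a resistor `Rbar`, a
#' capacitor `C1` to ground, an inductor `L1` in series with a resistor `R1`,
#' and the connecting node with capacitance `C` (which also receives the
#' coupling inflow `Q`). State vector `y = (pi, pi1, Q1)`.
#'
#' The state matrix is
#' \preformatted{
#'       [ 0         0          -1/C     ]
#'   A = [ 0     -1/(Rbar C1)    1/C1    ]
#'       [ 1/L1     -1/L1       -R1/L1   ]
#' }
#' with source `s(t) = (0, pbar(t)/(Rbar C1), 0)` and `U = diag(C, C1, L1)`.
#' Its dissipation form reduces to `pi1^2/Rbar + R1 Q1^2` (the connecting
#' node itself is lossless, so `B` is only positive semidefinite).
#'
#' @param Rbar,R1 resistances (N s m^-5), positive.
#' @param C,C1 capacitances (m^5 N^-1), positive; `C` is the connection
#'   capacitance.
#' @param L1 inductance (N s^2 m^-5), positive.
#' @param pbar source pressure `function(t)` (Pa); default zero.
#' @return A [circuit_model()].
#' @export
example_circuit <- function(Rbar = 1, R1 = 1, C = 0.1, C1 = 0.1, L1 = 1,
                            pbar = NULL) {
  vals <- c(Rbar = Rbar, R1 = R1, C = C, C1 = C1, L1 = L1)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all circuit parameters (Rbar, R1, C, C1, L1) must be positive")
  }
  if (is.null(pbar)) pbar <- function(t) rep(0, length(t))
  A <- rbind(
    c(0,            0,        -1 / C),
    c(0, -1 / (Rbar * C1),  1 / C1),
    c(1 / L1,   -1 / L1, -R1 / L1)
  )
  s <- function(t) c(0, pbar(t) / (Rbar * C1), 0)
  circuit_model(A, c(C, C1, L1), s = s, C_conn = C,
                params = c(as.list(vals), list(pbar = pbar)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_U_vector <- function(model) {
  if (inherits(model, "circuit_model")) return(model$U)
  if (is.matrix(model)) return(diag(model))
  as.numeric(model)
}

#' Circuit stored energy
#'
#' Energy held in the capacitors and inductors, `y' U y / 2`.
#'
#' @param model a [circuit_model()], a diagonal matrix, or the vector of
#'   diagonal entries of `U`.
#' @param y state vector.
#' @return Nonnegative scalar.
#' @export
circuit_energy <- function(model, y) {
  U <- as_U_vector(model)
  if (length(y) != length(U)) stop("dimension mismatch between 'U' and 'y'")
  0.5 * sum(U * y^2)
}

#' Circuit dissipation quadratic form
#'
#' Instantaneous power dissipated in the resistive elements, `y' B y` with
#' `B = -U A`. Nonnegative for passive networks (possibly zero on lossless
#' state directions).
#'
#' @param model a [circuit_model()] or the matrix `B` itself.
#' @param y state vector.
#' @return Scalar `y' B y`.
#' @export
circuit_dissipation <- function(model, y) {
  B <- if (inherits(model, "circuit_model")) model$B else as.matrix(model)
  if (length(y) != nrow(B)) stop("dimension mismatch between 'B' and 'y'")
  drop(crossprod(y, B %*% y))
}

#' Exact circuit trajectory by variation of constants
#'
#' Evaluates `y(t) = e^{At} y0 + int_0^t e^{A(t-tau)} (s(tau) + b Q(tau))
#' dtau` with the matrix exponential. Sources are represented as piecewise
#' constant on a uniform micro-grid, sampled at interval midpoints, and each
#' micro-interval is integrated exactly via an augmented-matrix exponential
#' (which also handles singular `A`). Midpoint sampling makes the scheme
#' second order in the micro step, so with the default resolution this
#' routine serves as a reference ("oracle") for the first-order Backward
#' Euler stepper.
#'
#' @param model a [circuit_model()].
#' @param Q flow-rate input `function(t)` (m^3/s); `NULL` for zero.
#' @param y0 initial state at `t_grid[1]`.
#' @param t_grid increasing vector of output times (s).
#' @param micro_n number of micro-intervals spread over the full span of
#'   `t_grid` (default 1e4).
#' @return List with `t` (the grid) and `y` (length(t) x d matrix of states).
#' @export
solve_circuit_exact <- function(model, Q = NULL, y0, t_grid, micro_n = 1e4) {
  stopifnot(inherits(model, "circuit_model"))
  d <- model$d
  if (length(y0) != d) stop("'y0' has wrong length")
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1 || is.unsorted(t_grid, strictly = TRUE) && length(t_grid) > 1)
    stop("'t_grid' must be strictly increasing")
  if (is.null(Q)) Q <- function(t) rep(0, length(t))
  e1 <- c(1, rep(0, d - 1))
  Y <- matrix(NA_real_, length(t_grid), d)
  Y[1, ] <- y0
  if (length(t_grid) == 1L) return(list(t = t_grid, y = Y))
  Tspan <- t_grid[length(t_grid)] - t_grid[1]
  cache <- new.env(parent = emptyenv())
  prop <- function(dt) {
    key <- format(dt, digits = 17)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    aug <- rbind(cbind(model$A, diag(d)), matrix(0, d, 2 * d))
    E <- as.matrix(Matrix::expm(Matrix::Matrix(aug * dt)))
    val <- list(E = E[1:d, 1:d, drop = FALSE],
                Phi = E[1:d, (d + 1):(2 * d), drop = FALSE])
    assign(key, val, envir = cache)
    val
  }
  y <- y0
  for (i in seq_len(length(t_grid) - 1L)) {
    t0 <- t_grid[i]; t1 <- t_grid[i + 1L]
    m <- max(1L, ceiling(micro_n * (t1 - t0) / Tspan))
    dt <- (t1 - t0) / m
    pr <- prop(dt)
    tm <- t0 + (seq_len(m) - 0.5) * dt
    for (j in seq_len(m)) {
      cvec <- model$s(tm[j]) + e1 * (Q(tm[j]) / model$C_conn)
      y <- drop(pr$E %*% y + pr$Phi %*% cvec)
    }
    Y[i + 1L, ] <- y
  }
  list(t = t_grid, y = Y)
}

#' One Backward Euler step of the circuit ODE
#'
#' Solves `(I - dt A) y_{n+1} = y_n + dt (s(t_{n+1}) + b Q)`, with the
#' coupling inflow `Q` treated implicitly as a known value at the new time
#' level. For a passive circuit `I - dt A` is nonsingular for every
#' `dt > 0`.
#'
#' @param model a [circuit_model()].
#' @param y current state.
#' @param Q coupling flow-rate value at the new time level (set 0 for the
#'   internal-circuit-only substep).
#' @param dt time step (s), positive.
#' @param t_next new time level at which sources are evaluated.
#' @return The new state vector.
#' @export
step_circuit_be <- function(model, y, Q = 0, dt, t_next) {
  stopifnot(inherits(model, "circuit_model"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  d <- model$d
  if (length(y) != d) stop("'y' has wrong length")
  e1 <- c(1, rep(0, d - 1))
  M <- diag(d) - dt * model$A
  rhs <- y + dt * (model$s(t_next) + e1 * (Q / model$C_conn))
  out <- tryCatch(solve(M, rhs), error = function(e) {
    stop("Backward Euler circuit system is singular: ", conditionMessage(e))
  })
  drop(out)
}
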