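# Interface conditions on Sigma: pointwise (PPC) and integral (IPC)
# pressure continuity, in the Backward Euler eliminated form.

#' Coefficients of the discrete IPC Robin condition
#'
#' Backward Euler discretization of the connecting-node ODE
#' `C dpi/dt = Q = (P - pi)/R` gives
#' `pi_{n+1} = (R C pi_n + dt P_{n+1}) / (R C + dt)`. Substituting into the
#' pointwise interface law `K v.n = p - pi` turns the interface condition
#' into a Robin-type boundary condition with a nonlocal mean term:
#' \preformatted{
#'   K v.n - p + [dt/(RC+dt)] * (1/m_sigma) int_Sigma p = -[RC/(RC+dt)] pi_n
#' }
#' This function returns those coefficients together with the recovery map
#' for `pi_{n+1}`.
#'
#' @param R,C connection resistance and capacitance, positive.
#' @param dt time step (s), positive.
#' @param pi_n connecting-node pressure at the old time level (Pa).
#' @param K Robin coefficient `R * m_sigma`; positive.
#' @return List with `coef_flux = K`, `coef_p = -1`, `coef_mean =
#'   dt/(RC+dt)`, `rhs = -RC/(RC+dt) * pi_n`, `rhs_factor = RC/(RC+dt)`,
#'   and `pi_update(P)` returning `pi_{n+1}`.
#' @export
ipc_robin_coefficients <- function(R, C, dt, pi_n = 0, K = R) {
  if (any(c(R, C, dt, K) <= 0)) stop("'R', 'C', 'dt', 'K' must be positive")
  tau <- R * C
  list(
    coef_flux = K,
    coef_p = -1,
    coef_mean = dt / (tau + dt),
    rhs_factor = tau / (tau + dt),
    rhs = -tau / (tau + dt) * pi_n,
    pi_update = function(P) (tau * pi_n + dt * P) / (tau + dt)
  )
}

# Build the Step-1 (Biot + connection) Backward Euler solver for one
# time-step size. The left-hand side is time independent and factorized
# once; `solve(t_next, u_prev, pi_n)` advances one step.
#
# variant "ipc": bordered system with the extra scalar unknown P and the
#   defining row m_sigma * P - int_Sigma p = 0 (rank-one nonlocal term).
# variant "ppc": the Sigma-trace pressure unknowns are condensed into the
#   single scalar P (exact constraint, no penalty), and the flux unknown
#   Q = C (P - pi_n)/(RC + dt) closes the condensed row.
# variant "none": uncoupled Biot step (no Sigma terms).
build_step1 <- function(disc, coupling = NULL, dt) {
  if (dt <= 0) stop("'dt' must be positive")
  N <- disc$N; nu <- disc$nu; ncomp <- disc$ncomp
  variant <- if (is.null(coupling)) "none" else coupling$variant
  if (variant != "none" && is.null(disc$sigma)) {
    stop("mesh has no face labelled 'sigma'; cannot apply interface coupling")
  }
  Mfull <- rbind(
    cbind(disc$A_el, -Matrix::t(disc$D)),
    cbind(disc$D / dt, disc$Kp)
  )
  free <- disc$free
  pdof <- nu + seq_len(N)

  if (variant == "ipc") {
    R <- coupling$R; Cc <- coupling$C; K <- coupling$K
    tau <- R * Cc
    m_vec <- disc$sigma$m_vec
    # add (1/K) * M_sig on the pressure block
    Ms <- disc$sigma$M_sig
    idx <- Matrix::summary(methods::as(Ms, "TsparseMatrix"))
    Madd <- Matrix::sparseMatrix(i = nu + idx$i, j = nu + idx$j,
                                 x = idx$x / K, dims = dim(Mfull))
    Mfull <- Mfull + Madd
    Mr <- Mfull[free, free]
    cvec <- numeric(disc$ndof)
    cvec[pdof] <- -(dt / ((tau + dt) * K)) * m_vec
    rvec <- numeric(disc$ndof)
    rvec[pdof] <- -m_vec
    LHS <- rbind(
      cbind(Mr, cvec[free]),
      c(rvec[free], disc$sigma$m_sigma)
    )
    fac <- Matrix::lu(methods::as(LHS, "CsparseMatrix"))
    solve_fn <- function(t_next, u_prev, pi_n) {
      lv <- load_vectors(disc, t_next)
      rhs <- numeric(disc$ndof)
      rhs[seq_len(nu)] <- lv$fu
      rhs[pdof] <- as.numeric(disc$D %*% u_prev) / dt + lv$fp +
        (tau / ((tau + dt) * K)) * pi_n * m_vec
      x <- Matrix::solve(fac, c(rhs[free], 0))
      xf <- numeric(disc$ndof)
      xf[free] <- x[seq_along(free)]
      P <- x[length(x)]
      pi_new <- (tau * pi_n + dt * P) / (tau + dt)
      list(u = xf[seq_len(nu)], p = xf[pdof], P = P,
           pi_new = pi_new, Q = (P - pi_new) / R, loads = lv)
    }
  } else if (variant == "ppc") {
    R <- coupling$R; Cc <- coupling$C
    tau <- R * Cc
    trace_p <- nu + disc$sigma$pnodes
    Mr <- Mfull[free, free]
    # map free dofs -> reduced dofs (trace pressures tied to the scalar P)
    is_tr <- free %in% trace_p
    nred <- sum(!is_tr) + 1L
    colmap <- integer(length(free))
    colmap[!is_tr] <- seq_len(sum(!is_tr))
    colmap[is_tr] <- nred
    Tmap <- Matrix::sparseMatrix(i = seq_along(free), j = colmap, x = 1,
                                 dims = c(length(free), nred))
    LHS <- Matrix::t(Tmap) %*% Mr %*% Tmap
    LHS[nred, nred] <- LHS[nred, nred] + Cc / (tau + dt)
    fac <- Matrix::lu(methods::as(LHS, "CsparseMatrix"))
    solve_fn <- function(t_next, u_prev, pi_n) {
      lv <- load_vectors(disc, t_next)
      rhs <- numeric(disc$ndof)
      rhs[seq_len(nu)] <- lv$fu
      rhs[pdof] <- as.numeric(disc$D %*% u_prev) / dt + lv$fp
      rr <- as.numeric(Matrix::t(Tmap) %*% rhs[free])
      rr[nred] <- rr[nred] + Cc * pi_n / (tau + dt)
      xr <- Matrix::solve(fac, rr)
      xf <- numeric(disc$ndof)
      xf[free] <- as.numeric(Tmap %*% xr)
      P <- xr[nred]
      Q <- Cc * (P - pi_n) / (tau + dt)
      pi_new <- pi_n + dt * Q / Cc
      list(u = xf[seq_len(nu)], p = xf[pdof], P = P,
           pi_new = pi_new, Q = Q, loads = lv)
    }
  } else {
    Mr <- Mfull[free, free]
    fac <- Matrix::lu(methods::as(Mr, "CsparseMatrix"))
    solve_fn <- function(t_next, u_prev, pi_n = 0) {
      lv <- load_vectors(disc, t_next)
      rhs <- numeric(disc$ndof)
      rhs[seq_len(nu)] <- lv$fu
      rhs[pdof] <- as.numeric(disc$D %*% u_prev) / dt + lv$fp
      x <- Matrix::solve(fac, rhs[free])
      xf <- numeric(disc$ndof)
      xf[free] <- as.numeric(x)
      list(u = xf[seq_len(nu)], p = xf[pdof], P = NA_real_,
           pi_new = NA_real_, Q = NA_real_, loads = lv)
    }
  }
  list(variant = variant, dt = dt, solve = solve_fn, Mfull = Mfull)
}

#' Interface pressure and flux statistics
#'
#' Boundary-quadrature evaluations on the coupling interface: the mean
#' pressure `(1/m_sigma) int_Sigma p`, the extrema of the pressure trace,
#' and the discharge `int_Sigma v.n` computed from the element-wise Darcy
#' flux `-k dp/dn` of the interface-adjacent elements.
#'
#' @param disc a [biot_discretization()] whose mesh has a `sigma` face.
#' @param p pressure nodal vector.
#' @return List with `P_mean`, `p_max`, `p_min`, `Q`.
#' @export
interface_statistics <- function(disc, p) {
  if (is.null(disc$sigma)) stop("discretization has no 'sigma' interface")
  sg <- disc$sigma
  tr <- p[sg$pnodes]
  list(P_mean = sum(sg$m_vec * p) / sg$m_sigma,
       p_max = max(tr), p_min = min(tr),
       Q = sum(sg$flux_row * p))
}

#' Connection dissipation
#'
#' Power dissipated in the connecting resistor: `R Q^2` for the pointwise
#' variant; `(1/K) int_Sigma (p - pi)^2` for the integral variant. Both are
#' nonnegative by construction.
#'
#' @param variant `"ppc"` or `"ipc"`.
#' @param spec a [coupling_spec()].
#' @param Q flow rate (PPC) (m^3/s).
#' @param disc,p,pi_val discretization, pressure vector and connecting-node
#'   pressure (IPC).
#' @return Nonnegative scalar (W-equivalent).
#' @export
connection_dissipation <- function(variant, spec, Q = NULL, disc = NULL,
                                   p = NULL, pi_val = NULL) {
  variant <- match.arg(tolower(variant), c("ppc", "ipc"))
  if (variant == "ppc") {
    if (is.null(Q)) stop("PPC dissipation needs 'Q'")
    return(spec$R * Q^2)
  }
  if (is.null(disc) || is.null(p) || is.null(pi_val)) {
    stop("IPC dissipation needs 'disc', 'p' and 'pi_val'")
  }
  sg <- disc$sigma
  (as.numeric(crossprod(p, sg$M_sig %*% p)) - 2 * pi_val * sum(sg$m_vec * p) +
      pi_val^2 * sg$m_sigma) / spec$K
}
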