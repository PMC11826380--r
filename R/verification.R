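# Analytic oracles and preset test problems.

#' Steady state of the coupled 1D--0D problem
#'
#' With constant boundary traction `g` (axial stress at x = 0) and constant
#' circuit source pressure `pbar`, all time derivatives vanish and the
#' coupled column--circuit system has the closed-form rest state: zero
#' discharge everywhere (`v = 0`, `Q = Q1 = 0`), uniform pore pressure
#' `p = pbar`, circuit pressures `pi = pi1 = pbar`, uniform total stress
#' `T = g`, and the linear displacement profile
#' `u(x) = (g + pbar)/H_A * (x - c)` (clamped at the interface).
#'
#' @param params a [poro_params()].
#' @param g constant axial stress at the loaded end (Pa), sign convention
#'   `T(0) = g`.
#' @param pbar constant source pressure (Pa).
#' @param geometry a [geometry_box()].
#' @return Object of class `steady_state_1d0d`: scalars `p_inf`, `pi_inf`,
#'   `pi1_inf`, `Q1_inf`, `T_inf`, `strain_inf` and the profile function
#'   `u_inf(x)`.
#' @export
steady_state_1d0d <- function(params, g, pbar, geometry) {
  stopifnot(inherits(params, "poro_params"), inherits(geometry, "poro_geometry"))
  strain <- (g + pbar) / params$H_A
  c_len <- geometry$c_len
  structure(list(
    p_inf = pbar, pi_inf = pbar, pi1_inf = pbar, Q_inf = 0, Q1_inf = 0,
    T_inf = g, strain_inf = strain,
    u_inf = function(x) strain * (x - c_len)
  ), class = "steady_state_1d0d")
}

#' @export
print.steady_state_1d0d <- function(x, ...) {
  cat("<steady_state_1d0d> p =", x$p_inf, "Pa, strain =", x$strain_inf,
      ", T =", x$T_inf, "Pa\n")
  invisible(x)
}

#' Truly three-dimensional boundary forcing (oscillatory infiltration)
#'
#' Prescribed normal filtration velocity on two faces of the
#' 0.5 x 0.1 x 0.1 box: a standing cosine pattern on the face x = 0
#' (period 10 s in time) and a travelling-free Gaussian spot on the face
#' y = -0.05 (period 20/3 s). All other points are rejected.
#'
#' * face x = 0: `-0.2 cos(10 pi y) cos(10 pi z) (1 + 0.5 cos(0.2 pi t))`
#' * face y = -0.05: `0.2 exp(-1000((x-0.45)^2 + z^2)) (1 - 0.5 sin(0.3 pi t))`
#'
#' @param x `n x 3` matrix of points lying on one of the two faces.
#' @param t time (s).
#' @param face `"auto"` (classify each point), `"x0"`, or `"ymin"`.
#' @return length-n vector of `v.n` values (m/s).
#' @export
forcing_infiltration <- function(x, t, face = c("auto", "x0", "ymin")) {
  face <- match.arg(face)
  x <- matrix(x, ncol = 3)
  tol <- 1e-9
  on_x0 <- abs(x[, 1]) < tol
  on_ym <- abs(x[, 2] + 0.05) < tol
  sel_x0 <- switch(face, auto = on_x0, x0 = rep(TRUE, nrow(x)),
                   ymin = rep(FALSE, nrow(x)))
  if (face == "x0" && !all(on_x0)) stop("points not on the face x = 0")
  if (face == "ymin" && !all(on_ym)) stop("points not on the face y = -0.05")
  if (face == "auto" && !all(on_x0 | on_ym)) {
    stop("points must lie on the face x = 0 or y = -0.05")
  }
  out <- numeric(nrow(x))
  i1 <- which(sel_x0)
  i2 <- which(!sel_x0)
  if (length(i1)) {
    out[i1] <- -0.2 * cos(10 * pi * x[i1, 2]) * cos(10 * pi * x[i1, 3]) *
      (1 + 0.5 * cos(0.2 * pi * t))
  }
  if (length(i2)) {
    out[i2] <- 0.2 * exp(-1000 * ((x[i2, 1] - 0.45)^2 + x[i2, 3]^2)) *
      (1 - 0.5 * sin(0.3 * pi * t))
  }
  out
}

# reference material / circuit values used by the preset problems:
# permeability 1, aggregate modulus 1 (split lambda=0.5, mu=0.25),
# all resistances 1, capacitances 0.1, inductance 1.
preset_params <- function() poro_params(lambda_e = 0.5, mu_e = 0.25, k = 1)

preset_circuit <- function(pbar = NULL) {
  example_circuit(Rbar = 1, R1 = 1, C = 0.1, C1 = 0.1, L1 = 1, pbar = pbar)
}

#' One-dimension-conducive 3D preset (oscillatory source)
#'
#' Builds the 3D box problem (0.5 x 0.1 x 0.1 m) whose geometry, boundary
#' conditions and x-only forcing admit a one-dimensional solution: traction
#' face at x = 0 (zero traction), sliding impermeable lateral walls, the
#' coupling interface at x = 0.5, and all forcing supplied by the circuit
#' source pressure `pbar(t) = amp * sin(2 pi t / period)`. The amplitude is
#' auto-scaled by linearity so that the peak interface pressure over the
#' run equals `scale`: a cheap 1D run with unit amplitude measures the peak
#' response, and `amp = scale / peak`. The matched 1D column problem (same
#' parameters and forcing) is returned alongside.
#'
#' @param scale target peak interface pressure (Pa), positive.
#' @param variant interface condition, `"ipc"` or `"ppc"`.
#' @param n 3D mesh cells per axis.
#' @param type element type for the 3D mesh (`"hex"` recommended: the
#'   tensor-product basis preserves the 1D invariance exactly).
#' @param nx1d intervals of the 1D calibration/companion grid.
#' @param dt,t_end time grid (s) used for calibration and intended runs.
#' @param period source period (s).
#' @return List with `problem` (3D), `problem_1d`, `amp`, `dt`, `t_end`,
#'   `pbar`, `coupling`, `params`.
#' @export
preset_oned_conducive <- function(scale = 0.1, variant = "ipc", n = c(12, 5, 5),
                          type = "hex", nx1d = 50, dt = 0.02, t_end = 10,
                          period = 5) {
  if (scale <= 0) stop("'scale' must be positive")
  params <- preset_params()
  geom <- geometry_box(0.5, 0.1, 0.1)
  cpl <- function(v) coupling_spec(v, R = 1, C = 0.1, m_sigma = geom$m_sigma)
  make_1d <- function(amp) {
    pb <- function(t) amp * sin(2 * pi * t / period)
    disc <- biot_discretization(mesh_interval(geom, nx1d), params,
                                forcing_data())
    biot0d_problem(disc, preset_circuit(pb), cpl(variant))
  }
  cal <- run_operator_splitting(make_1d(1), dt = dt, t_end = t_end)
  peak <- max(abs(cal$P))
  amp <- scale / peak
  pbar <- function(t) amp * sin(2 * pi * t / period)
  disc3 <- biot_discretization(mesh_box(geom, n, type), params,
                               forcing_data())
  list(problem = biot0d_problem(disc3, preset_circuit(pbar), cpl(variant)),
       problem_1d = make_1d(amp),
       amp = amp, dt = dt, t_end = t_end, pbar = pbar,
       coupling = cpl(variant), params = params, geometry = geom)
}

#' Fully three-dimensional preset (two-face infiltration forcing)
#'
#' The same box, circuit and connection as [preset_oned_conducive()], but driven by
#' the genuinely 3D infiltration pattern of [forcing_infiltration()] on the faces
#' x = 0 and y = -0.05 (both clamped, prescribed `v.n`); the remaining
#' lateral faces are sliding impermeable walls and the interface stays at
#' x = 0.5. No circuit source.
#'
#' @param variant interface condition, `"ipc"` or `"ppc"`.
#' @param n mesh cells per axis.
#' @param type element type.
#' @param dt,t_end time grid (s).
#' @return List with `problem`, `dt`, `t_end`.
#' @export
preset_infiltration <- function(variant = "ipc", n = c(12, 6, 6), type = "hex",
                          dt = 0.02, t_end = 10) {
  params <- preset_params()
  geom <- geometry_box(0.5, 0.1, 0.1,
                       faces = list(xmin = "gammaDv", ymin = "gammaDv"))
  psi <- function(x, t) forcing_infiltration(x, t, face = "auto")
  disc <- biot_discretization(mesh_box(geom, n, type), params,
                              forcing_data(psi = psi))
  cpl <- coupling_spec(variant, R = 1, C = 0.1, m_sigma = geom$m_sigma)
  list(problem = biot0d_problem(disc, preset_circuit(NULL), cpl),
       dt = dt, t_end = t_end)
}

#' Constant-forcing 1D preset (steady-state relaxation)
#'
#' 1D column with constant axial stress `g` at x = 0 and constant circuit
#' source pressure `pbar`; time stepping from rest converges geometrically
#' to the [steady_state_1d0d()] rest state.
#'
#' @param g constant axial stress at x = 0 (Pa), convention `T(0) = g`.
#' @param pbar constant source pressure (Pa).
#' @param variant interface condition.
#' @param nx grid intervals.
#' @return List with `problem`, `oracle` (the steady state), `params`,
#'   `geometry`.
#' @export
preset_steady1d <- function(g = 0, pbar = 1, variant = "ipc", nx = 50) {
  params <- preset_params()
  geom <- geometry_box(0.5, 0.1, 0.1)
  # weak form takes the traction vector T.n; at x = 0 the outward normal is
  # -e_x, so prescribing T(0) = g means the traction datum is -g.
  gfun <- if (g != 0) function(x, t) matrix(-g, nrow(x), 1) else NULL
  disc <- biot_discretization(mesh_interval(geom, nx), params,
                              forcing_data(g = gfun))
  cpl <- coupling_spec(variant, R = 1, C = 0.1, m_sigma = geom$m_sigma)
  circ <- preset_circuit(function(t) rep(pbar, length(t)))
  list(problem = biot0d_problem(disc, circ, cpl),
       oracle = steady_state_1d0d(params, g, pbar, geom),
       params = params, geometry = geom)
}
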