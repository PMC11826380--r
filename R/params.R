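#' Poroelastic material parameters
#'
#' Quasi-static Biot medium with incompressible constituents: storage
#' coefficient fixed at zero and Biot--Willis coefficient fixed at one. The
#' aggregate (confined-compression) modulus `H_A = lambda_e + 2 mu_e` is the
#' stiffness governing the reduced 1D column model.
#'
#' @param lambda_e first Lame parameter (Pa), nonnegative.
#' @param mu_e shear modulus (Pa), positive.
#' @param k permeability (m^4 N^-1 s^-1), positive.
#' @return Object of class `poro_params` with fields `lambda_e`, `mu_e`,
#'   `k`, `H_A`, `alpha = 1`, `c0 = 0`.
#' @export
poro_params <- function(lambda_e, mu_e, k) {
  if (!is.numeric(mu_e) || mu_e <= 0) stop("'mu_e' must be positive")
  if (!is.numeric(lambda_e) || lambda_e < 0) stop("'lambda_e' must be nonnegative")
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive")
  structure(list(lambda_e = lambda_e, mu_e = mu_e, k = k,
                 H_A = lambda_e + 2 * mu_e, alpha = 1, c0 = 0),
            class = "poro_params")
}

#' @export
print.poro_params <- function(x, ...) {
  cat("<poro_params> lambda_e =", x$lambda_e, "Pa, mu_e =", x$mu_e,
      "Pa, k =", x$k, "m^4/(N s), H_A =", x$H_A, "Pa\n")
  invisible(x)
}

face_labels <- c("gammaN", "gammaDp", "gammaDv", "gamma0", "sigma")
box_sides <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")

#' Box geometry and boundary partition
#'
#' The domain is the box `(0, c) x (-a/2, a/2) x (-b/2, b/2)`. Each of the
#' six faces carries one boundary label:
#' * `"gammaN"`  -- prescribed traction `T n = g`, impermeable (`v.n = 0`);
#' * `"gammaDp"` -- clamped (`u = 0`), drained (`p = 0`);
#' * `"gammaDv"` -- clamped (`u = 0`), prescribed filtration `v.n = psi`;
#' * `"gamma0"`  -- sliding wall (`u.n = 0`, zero tangential traction),
#'   impermeable;
#' * `"sigma"`   -- the 3D--0D coupling interface (`u = 0` plus the variant's
#'   pressure/flux conditions).
#' By default the interface sits at `x = c` (area `m_sigma = a*b`), the face
#' `x = 0` is traction-loaded and the four lateral faces slide.
#'
#' The same object describes the reduced 1D column on `(0, c)` (only the
#' `xmin`/`xmax` labels are used there; volume integrals carry the
#' cross-section factor `a*b` so that 1D and 3D runs report comparable
#' energies and flow rates).
#'
#' @param c_len,a,b box edge lengths along x, y, z (m), positive.
#' @param faces named list mapping sides `xmin`, `xmax`, `ymin`, `ymax`,
#'   `zmin`, `zmax` to labels; partially specified lists override the
#'   default.
#' @return Object of class `poro_geometry` with fields `c_len`, `a`, `b`,
#'   `faces`, `sigma_side`, `m_sigma`.
#' @export
geometry_box <- function(c_len = 0.5, a = 0.1, b = 0.1, faces = list()) {
  if (any(c(c_len, a, b) <= 0)) stop("box dimensions must be positive")
  def <- list(xmin = "gammaN", xmax = "sigma", ymin = "gamma0",
              ymax = "gamma0", zmin = "gamma0", zmax = "gamma0")
  if (length(faces)) {
    bad <- setdiff(names(faces), box_sides)
    if (length(bad)) stop("unknown face side(s): ", paste(bad, collapse = ", "))
    def[names(faces)] <- faces
  }
  lab <- unlist(def)
  bad <- setdiff(lab, face_labels)
  if (length(bad)) stop("unknown face label(s): ", paste(bad, collapse = ", "))
  sig <- names(def)[lab == "sigma"]
  if (length(sig) > 1) stop("at most one face may be labelled 'sigma'")
  m_sigma <- if (length(sig) == 1) {
    switch(substr(sig, 1, 1), x = a * b, y = c_len * b, z = c_len * a)
  } else NA_real_
  structure(list(c_len = c_len, a = a, b = b, faces = def,
                 sigma_side = if (length(sig)) sig else NULL,
                 m_sigma = m_sigma),
            class = "poro_geometry")
}

#' @export
print.poro_geometry <- function(x, ...) {
  cat("<poro_geometry> box", x$c_len, "x", x$a, "x", x$b, "m\n")
  cat("  faces:", paste(names(x$faces), unlist(x$faces), sep = "=",
                        collapse = " "), "\n")
  if (!is.null(x$sigma_side))
    cat("  interface on", x$sigma_side, ", area", x$m_sigma, "m^2\n")
  invisible(x)
}

#' Interface coupling specification
#'
#' Connection between the poroelastic interface and the circuit: a resistor
#' `R` obeying the hydraulic Ohm law `Q = (P - pi)/R` and a capacitor `C` to
#' ground at the connecting node. The Robin coefficient of the integral
#' variant is `K = R * m_sigma` (derived, never user-set).
#'
#' @param variant `"ppc"` (pointwise pressure continuity: `p` constant on
#'   the interface) or `"ipc"` (integral continuity: `K v.n = p - pi`
#'   pointwise, `P` the interface mean of `p`).
#' @param R connecting resistance (N s m^-5), positive.
#' @param C connecting capacitance (m^5 N^-1), positive. Must match the
#'   connecting-node capacitance of the circuit model it is used with.
#' @param m_sigma interface measure (m^2), positive.
#' @return Object of class `coupling_spec` with derived field `K`.
#' @export
coupling_spec <- function(variant = c("ipc", "ppc"), R, C, m_sigma) {
  variant <- match.arg(tolower(variant), c("ipc", "ppc"))
  if (!is.numeric(R) || R <= 0) stop("'R' must be positive")
  if (!is.numeric(C) || C <= 0) stop("'C' must be positive")
  if (!is.numeric(m_sigma) || m_sigma <= 0) stop("'m_sigma' must be positive")
  structure(list(variant = variant, R = R, C = C, m_sigma = m_sigma,
                 K = R * m_sigma),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat("<coupling_spec>", toupper(x$variant), " R =", x$R, " C =", x$C,
      " |Sigma| =", x$m_sigma, " K =", x$K, "\n")
  invisible(x)
}

#' Volume, boundary and initial forcing data
#'
#' All functions are vectorized over points: they receive an `n x dim`
#' coordinate matrix `x` and a scalar time `t`.
#'
#' @param F body force, `function(x, t)` returning an `n x dim` matrix
#'   (N/m^3); `NULL` for zero.
#' @param S fluid source, `function(x, t)` returning length-n (1/s); `NULL`
#'   for zero.
#' @param g traction vector on `gammaN` faces, `function(x, t)` returning an
#'   `n x dim` matrix (Pa); `NULL` for zero. This is the traction `T n`
#'   including the outward-normal orientation.
#' @param psi prescribed normal filtration velocity `v.n` on `gammaDv`
#'   faces, `function(x, t)` returning length-n (m/s); `NULL` for zero.
#' @param u0 initial displacement, `function(x)` returning `n x dim` (m);
#'   `NULL` for zero.
#' @param y0 initial circuit state vector; `NULL` for zero.
#' @return Object of class `forcing_data`.
#' @export
forcing_data <- function(F = NULL, S = NULL, g = NULL, psi = NULL,
                         u0 = NULL, y0 = NULL) {
  chk <- function(f, nm) {
    if (!is.null(f) && !is.function(f)) stop("'", nm, "' must be a function or NULL")
    f
  }
  structure(list(F = chk(F, "F"), S = chk(S, "S"), g = chk(g, "g"),
                 psi = chk(psi, "psi"), u0 = chk(u0, "u0"), y0 = y0),
            class = "forcing_data")
}
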