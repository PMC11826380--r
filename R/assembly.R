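# Finite element discretization of the quasi-static Biot system.
#
# Global dof ordering: displacement components stacked first
# (u_1 nodes, u_2 nodes, u_3 nodes), then pressure nodes. All matrices are
# scaled by the cross-section factor a*b when the mesh is the reduced 1D
# column, so energies and flow rates are directly comparable with 3D runs.

assemble_shared <- function(elems, Kloc, N, roff = 0, coff = 0,
                            dims = NULL) {
  nn <- ncol(elems)
  ne <- nrow(elems)
  ii <- roff + as.vector(elems[, rep(seq_len(nn), times = nn), drop = FALSE])
  jj <- coff + as.vector(elems[, rep(seq_len(nn), each = nn), drop = FALSE])
  xx <- rep(as.vector(Kloc), each = ne)
  if (is.null(dims)) dims <- c(N + roff, N + coff)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = dims)
}

# per-element local quantities for the three element types
local_ops <- function(mesh) {
  if (mesh$type == "interval") {
    h <- mesh$h
    g <- gauss1
    xi <- c(-g, g)                     # on [-1, 1]
    phi <- cbind((1 - xi) / 2, (1 + xi) / 2)
    dphi <- array(0, c(2, 2, 1))
    dphi[, 1, 1] <- -1 / h
    dphi[, 2, 1] <- 1 / h
    w <- rep(h / 2, 2)
    list(shared = TRUE, nq = 2L, nn = 2L, phi = phi, dphi = dphi, w = w)
  } else if (mesh$type == "hex") {
    qa <- hex_gauss()
    hb <- hex_basis(qa$pts)
    dphi <- hb$dphi
    for (c_ in 1:3) dphi[, , c_] <- dphi[, , c_] * (2 / mesh$h[c_])
    w <- qa$w * prod(mesh$h) / 8
    list(shared = TRUE, nq = 8L, nn = 8L, phi = hb$phi, dphi = dphi, w = w,
         qpts_ref = qa$pts)
  } else {  # tet
    qa <- tet_gauss()
    lam <- cbind(1 - rowSums(qa$pts), qa$pts)  # barycentric at quad points
    ne <- nrow(mesh$elems)
    grads <- array(NA_real_, c(ne, 4, 3))
    vol <- numeric(ne)
    for (e in seq_len(ne)) {
      X <- mesh$nodes[mesh$elems[e, ], ]
      Cmat <- cbind(1, X)
      Ci <- solve(Cmat)
      grads[e, , ] <- t(Ci[2:4, , drop = FALSE])
      vol[e] <- abs(det(Cmat)) / 6
    }
    list(shared = FALSE, nq = 4L, nn = 4L, phi = lam, wref = qa$w * 6,
         grads = grads, vol = vol)
  }
}

# gauss point coordinates for every element, stacked (ne*nq) x dim
gauss_coords <- function(mesh, ops) {
  ne <- nrow(mesh$elems)
  if (mesh$type == "interval") {
    x0 <- mesh$nodes[mesh$elems[, 1], 1]
    g <- gauss1
    loc <- (c(-g, g) + 1) / 2 * mesh$h
    xq <- matrix(rep(x0, each = ops$nq) + rep(loc, times = ne), ncol = 1)
  } else if (mesh$type == "hex") {
    corner <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
    loc <- sweep((ops$qpts_ref + 1) / 2, 2, mesh$h, `*`)  # nq x 3
    xq <- matrix(NA_real_, ne * ops$nq, 3)
    for (q in seq_len(ops$nq)) {
      xq[seq(q, by = ops$nq, length.out = ne), ] <-
        sweep(corner, 2, loc[q, ], `+`)
    }
  } else {
    xq <- matrix(NA_real_, ne * ops$nq, 3)
    for (e in seq_len(ne)) {
      X <- mesh$nodes[mesh$elems[e, ], ]
      xq[(e - 1) * ops$nq + seq_len(ops$nq), ] <- ops$phi %*% X
    }
  }
  xq
}

side_axis <- c(xmin = 1L, xmax = 1L, ymin = 2L, ymax = 2L,
               zmin = 3L, zmax = 3L)
side_sign <- c(xmin = -1, xmax = 1, ymin = -1, ymax = 1, zmin = -1, zmax = 1)
quad_signs <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))

# boundary facet quadrature structures for one side of a 3D mesh:
# load operator L (N x nfq), gauss coords, facet mass matrix (N x N),
# and an integrated normal-flux row for -k dp/dn.
face_structures <- function(mesh, side, k_perm) {
  bf <- mesh$bfaces[[side]]
  N <- nrow(mesh$nodes)
  if (is.null(bf$nodes) || nrow(bf$nodes) == 0) return(NULL)
  nf <- nrow(bf$nodes)
  tri <- ncol(bf$nodes) == 3
  if (tri) {
    qa <- tri_gauss()
    lam <- cbind(1 - rowSums(qa$pts), qa$pts)
    nq <- 3L
  } else {
    qa <- quad_gauss()
    phiF <- matrix(NA_real_, 4, 4)
    for (a in 1:4) {
      phiF[, a] <- (1 + quad_signs[a, 1] * qa$pts[, 1]) *
        (1 + quad_signs[a, 2] * qa$pts[, 2]) / 4
    }
    nq <- 4L
  }
  ii <- jj <- integer(0); xx <- numeric(0)
  mi <- mj <- integer(0); mx <- numeric(0)
  fr <- numeric(N)
  xqf <- matrix(NA_real_, nf * nq, 3)
  ax <- side_axis[[side]]
  sgn <- side_sign[[side]]
  for (f in seq_len(nf)) {
    fn <- bf$nodes[f, ]
    X <- mesh$nodes[fn, , drop = FALSE]
    if (tri) {
      e1 <- X[2, ] - X[1, ]; e2 <- X[3, ] - X[1, ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      area2 <- sqrt(sum(cr^2))            # = 2 * area
      wq <- qa$w * area2                  # area/3 each
      phi_here <- lam
    } else {
      A1 <- sqrt(sum((X[2, ] - X[1, ])^2))
      A2 <- sqrt(sum((X[4, ] - X[1, ])^2))
      wq <- qa$w * A1 * A2 / 4
      phi_here <- phiF
    }
    pts <- phi_here %*% X
    xqf[(f - 1) * nq + seq_len(nq), ] <- pts
    # load operator triplets
    for (a in seq_along(fn)) {
      ii <- c(ii, rep(fn[a], nq))
      jj <- c(jj, (f - 1) * nq + seq_len(nq))
      xx <- c(xx, wq * phi_here[, a])
    }
    # facet mass
    Mloc <- t(phi_here) %*% (wq * phi_here)
    mi <- c(mi, rep(fn, times = length(fn)))
    mj <- c(mj, rep(fn, each = length(fn)))
    mx <- c(mx, as.vector(Mloc))
    # normal flux row from parent element gradients
    e <- bf$parent[f]
    en <- mesh$elems[e, ]
    if (mesh$type == "hex") {
      corner <- mesh$nodes[en[1], ]
      xi <- sweep(sweep(pts, 2, corner, `-`), 2, mesh$h, `/`) * 2 - 1
      hb <- hex_basis(xi)
      dn <- hb$dphi[, , ax] * (2 / mesh$h[ax])   # nq x 8
      fr[en] <- fr[en] - k_perm * sgn * colSums(wq * dn)
    } else {
      lops_g <- attr(mesh, "tet_grads")
      gr <- lops_g$grads[e, , ax]
      fr[en] <- fr[en] - k_perm * sgn * sum(wq) * gr
    }
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, nf * nq))
  Mface <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(N, N))
  list(L = L, xq = xqf, M = Mface, flux_row = fr,
       nodes = sort(unique(as.vector(bf$nodes))))
}

#' Discretize the quasi-static Biot system on a mesh
#'
#' Assembles all time-independent operators of the Backward Euler
#' discretization of the incompressible-constituent Biot system: the elastic
#' stiffness (`2 mu int E(u):E(w) + lambda int div u div w`), the
#' displacement-pressure coupling `int q div u`, the Darcy stiffness
#' `k int grad p . grad q`, mass matrices, quadrature-based load operators
#' for volume and boundary forcing, per-side boundary structures, the
#' interface (Sigma) trace operators, and the constrained degree-of-freedom
#' bookkeeping implied by the boundary labels.
#'
#' @param mesh a [mesh_box()] or [mesh_interval()].
#' @param params a [poro_params()].
#' @param forcing a [forcing_data()] (may be `NULL` for homogeneous data).
#' @return Object of class `biot_disc`. Key fields: `A_el`, `D`, `Kp`, `Mp`
#'   (global sparse operators), `free` (unconstrained dof indices), `sigma`
#'   (interface trace structures: `M_sig`, `m_vec`, `m_sigma`, `flux_row`,
#'   `pnodes`), `loads(t)` is provided by [load_vectors()].
#' @export
biot_discretization <- function(mesh, params, forcing = NULL) {
  stopifnot(inherits(mesh, "poro_mesh"), inherits(params, "poro_params"))
  if (is.null(forcing)) forcing <- forcing_data()
  geom <- mesh$geometry
  dim <- mesh$dim
  ncomp <- dim
  N <- nrow(mesh$nodes)
  nu <- ncomp * N
  np <- N
  csf <- if (dim == 1) geom$a * geom$b else 1

  ops <- local_ops(mesh)
  if (mesh$type == "tet") attr(mesh, "tet_grads") <- ops
  elems <- mesh$elems
  ne <- nrow(elems)
  nn <- ops$nn

  if (ops$shared) {
    w <- ops$w
    G <- vector("list", ncomp)
    for (c_ in seq_len(ncomp)) {
      G[[c_]] <- vector("list", ncomp)
      for (d_ in seq_len(ncomp)) {
        G[[c_]][[d_]] <- t(ops$dphi[, , c_]) %*% (w * ops$dphi[, , d_])
      }
    }
    Mloc <- t(ops$phi) %*% (w * ops$phi)
    Kgrad <- Reduce(`+`, lapply(seq_len(ncomp), function(c_) G[[c_]][[c_]]))
    Dloc <- lapply(seq_len(ncomp), function(c_) t(ops$phi) %*% (w * ops$dphi[, , c_]))

    blk <- function(loc) assemble_shared(elems, loc, N)
    Kgrad_g <- blk(Kgrad)
    Mp <- csf * blk(Mloc)
    Kp <- csf * params$k * Kgrad_g
    A_el <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(nu, nu))
    for (c_ in seq_len(ncomp)) {
      for (d_ in seq_len(ncomp)) {
        loc <- params$mu_e * ((c_ == d_) * Kgrad + G[[d_]][[c_]]) +
          params$lambda_e * G[[c_]][[d_]]
        A_el <- A_el + assemble_shared(elems, loc, N,
                                       roff = (c_ - 1) * N, coff = (d_ - 1) * N,
                                       dims = c(nu, nu))
      }
    }
    A_el <- csf * A_el
    D <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(np, nu))
    for (c_ in seq_len(ncomp)) {
      D <- D + assemble_shared(elems, Dloc[[c_]], N,
                               roff = 0, coff = (c_ - 1) * N,
                               dims = c(np, nu))
    }
    D <- csf * D
    # volume load operator triplets
    nq <- ops$nq
    ii <- jj <- integer(0); xx <- numeric(0)
    for (a in seq_len(nn)) {
      ii <- c(ii, rep(elems[, a], each = nq))
      jj <- c(jj, rep(seq_len(nq), times = ne) +
                rep((seq_len(ne) - 1) * nq, each = nq))
      xx <- c(xx, rep(w * ops$phi[, a], times = ne))
    }
    Lvol <- csf * Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                       dims = c(N, ne * nq))
  } else {
    # tetrahedra: per-element constant gradients, preallocated triplets
    nq <- ops$nq
    lam <- ops$phi
    Mref <- t(lam) %*% (rep(1 / 4, 4) * lam)  # unit-volume P1 mass (exact)
    n16 <- nn * nn
    iK <- jK <- matrix(0L, n16, ne); xK <- xM <- matrix(0, n16, ne)
    iA <- jA <- matrix(0L, 9 * n16, ne); xA <- matrix(0, 9 * n16, ne)
    iD <- jD <- matrix(0L, 3 * n16, ne); xD <- matrix(0, 3 * n16, ne)
    iL <- jL <- matrix(0L, nn * nq, ne); xL <- matrix(0, nn * nq, ne)
    for (e in seq_len(ne)) {
      en <- elems[e, ]
      gr <- ops$grads[e, , ]              # 4 x 3
      V <- ops$vol[e]
      Kploc <- V * gr %*% t(gr)
      idx <- rep(en, times = nn); jdx <- rep(en, each = nn)
      iK[, e] <- idx; jK[, e] <- jdx
      xK[, e] <- as.vector(Kploc); xM[, e] <- as.vector(V * Mref)
      blk <- 0L
      for (c_ in seq_len(3)) {
        for (d_ in seq_len(3)) {
          loc <- params$mu_e * ((c_ == d_) * Kploc +
                                  V * outer(gr[, d_], gr[, c_])) +
            params$lambda_e * V * outer(gr[, c_], gr[, d_])
          rows <- blk * n16 + seq_len(n16)
          iA[rows, e] <- (c_ - 1) * N + idx
          jA[rows, e] <- (d_ - 1) * N + jdx
          xA[rows, e] <- as.vector(loc)
          blk <- blk + 1L
        }
        # int phi_a d_c phi_b = (V/4) * grad_b[c]
        rows <- (c_ - 1L) * n16 + seq_len(n16)
        iD[rows, e] <- idx
        jD[rows, e] <- (c_ - 1) * N + jdx
        xD[rows, e] <- as.vector(V * matrix(rep(gr[, c_], each = 4), 4, 4) / 4)
      }
      iL[, e] <- rep(en, each = nq)
      jL[, e] <- rep((e - 1L) * nq + seq_len(nq), times = nn)
      xL[, e] <- as.vector(matrix(V / 4 * lam, nq, nn))
    }
    A_el <- Matrix::sparseMatrix(i = as.vector(iA), j = as.vector(jA),
                                 x = as.vector(xA), dims = c(nu, nu))
    D <- Matrix::sparseMatrix(i = as.vector(iD), j = as.vector(jD),
                              x = as.vector(xD), dims = c(np, nu))
    Kp <- params$k * Matrix::sparseMatrix(i = as.vector(iK), j = as.vector(jK),
                                          x = as.vector(xK), dims = c(np, np))
    Mp <- Matrix::sparseMatrix(i = as.vector(iK), j = as.vector(jK),
                               x = as.vector(xM), dims = c(np, np))
    Lvol <- Matrix::sparseMatrix(i = as.vector(iL), j = as.vector(jL),
                                 x = as.vector(xL), dims = c(N, ne * nq))
  }
  xq <- gauss_coords(mesh, ops)

  # boundary structures per side
  faces <- list()
  if (dim == 3) {
    for (s in box_sides) {
      fs <- face_structures(mesh, s, params$k)
      if (!is.null(fs)) {
        fs$label <- geom$faces[[s]]
        fs$side <- s
        faces[[s]] <- fs
      }
    }
  } else {
    for (s in c("xmin", "xmax")) {
      nd <- mesh$bfaces[[s]]$nodes[1, 1]
      pe <- mesh$bfaces[[s]]$parent[1]
      en <- mesh$elems[pe, ]
      h <- mesh$h
      fr <- numeric(N)
      dsign <- side_sign[[s]]
      # -k dp/dn * csf : one-sided gradient of the parent interval element
      fr[en] <- -params$k * csf * dsign * c(-1, 1) / h
      faces[[s]] <- list(
        L = Matrix::sparseMatrix(i = nd, j = 1L, x = csf, dims = c(N, 1L)),
        xq = mesh$nodes[nd, , drop = FALSE],
        M = Matrix::sparseMatrix(i = nd, j = nd, x = csf, dims = c(N, N)),
        flux_row = fr, nodes = nd, label = geom$faces[[s]], side = s)
    }
  }

  # interface structures
  sigma <- NULL
  sig_sides <- names(faces)[vapply(faces, function(f) f$label == "sigma", TRUE)]
  if (length(sig_sides) == 1) {
    fs <- faces[[sig_sides]]
    m_vec <- as.numeric(fs$M %*% rep(1, N))
    sigma <- list(side = sig_sides, pnodes = fs$nodes, M_sig = fs$M,
                  m_vec = m_vec, m_sigma = sum(m_vec), flux_row = fs$flux_row)
  }

  # constrained dofs
  fixed_u <- rep(list(integer(0)), ncomp)
  fixed_p <- integer(0)
  axmap <- side_axis
  for (s in names(faces)) {
    f <- faces[[s]]
    nds <- f$nodes
    lab <- f$label
    if (lab %in% c("sigma", "gammaDp", "gammaDv")) {
      for (c_ in seq_len(ncomp)) fixed_u[[c_]] <- union(fixed_u[[c_]], nds)
      if (lab == "gammaDp") fixed_p <- union(fixed_p, nds)
    } else if (lab == "gamma0" && dim == 3) {
      ax <- axmap[[s]]
      fixed_u[[ax]] <- union(fixed_u[[ax]], nds)
    }
  }
  fixed <- integer(0)
  for (c_ in seq_len(ncomp)) fixed <- c(fixed, (c_ - 1) * N + fixed_u[[c_]])
  fixed <- c(fixed, ncomp * N + fixed_p)
  ndof <- nu + np
  free <- setdiff(seq_len(ndof), fixed)

  structure(list(
    mesh = mesh, params = params, geometry = geom, forcing = forcing,
    dim = dim, ncomp = ncomp, N = N, nu = nu, np = np, ndof = ndof,
    csf = csf, A_el = A_el, D = D, Kp = Kp, Mp = Mp,
    Lvol = Lvol, xq = xq, faces = faces, sigma = sigma,
    fixed_u = fixed_u, fixed_p = fixed_p, free = free
  ), class = "biot_disc")
}

#' @export
print.biot_disc <- function(x, ...) {
  cat("<biot_disc>", if (x$dim == 1) "1D" else "3D", "-", x$N, "nodes,",
      x$ndof, "dofs (", length(x$free), "free )\n")
  invisible(x)
}

#' Forcing load vectors at one time level
#'
#' Evaluates the volume and boundary forcing of a discretization at time
#' `t`: body force `F` and traction `g` (on `gammaN`) into the momentum
#' right-hand side, fluid source `S` and prescribed filtration `psi` (on
#' `gammaDv`, entering with a minus sign) into the mass right-hand side.
#'
#' @param disc a [biot_discretization()].
#' @param t time (s).
#' @return List with `fu` (length `ncomp*N`) and `fp` (length `N`).
#' @export
load_vectors <- function(disc, t) {
  N <- disc$N
  fu_vol <- numeric(disc$nu); fu_bnd <- numeric(disc$nu)
  fp_vol <- numeric(disc$np); fp_bnd <- numeric(disc$np)
  frc <- disc$forcing
  if (!is.null(frc$F)) {
    Fv <- matrix(frc$F(disc$xq, t), ncol = disc$ncomp)
    for (c_ in seq_len(disc$ncomp)) {
      fu_vol[(c_ - 1) * N + seq_len(N)] <- as.numeric(disc$Lvol %*% Fv[, c_])
    }
  }
  if (!is.null(frc$S)) {
    fp_vol <- as.numeric(disc$Lvol %*% frc$S(disc$xq, t))
  }
  for (f in disc$faces) {
    if (f$label == "gammaN" && !is.null(frc$g)) {
      gv <- matrix(frc$g(f$xq, t), ncol = disc$ncomp)
      for (c_ in seq_len(disc$ncomp)) {
        fu_bnd[(c_ - 1) * N + seq_len(N)] <- fu_bnd[(c_ - 1) * N + seq_len(N)] +
          as.numeric(f$L %*% gv[, c_])
      }
    }
    if (f$label == "gammaDv" && !is.null(frc$psi)) {
      fp_bnd <- fp_bnd - as.numeric(f$L %*% frc$psi(f$xq, t))
    }
  }
  list(fu = fu_vol + fu_bnd, fp = fp_vol + fp_bnd,
       fu_vol = fu_vol, fu_bnd = fu_bnd, fp_vol = fp_vol, fp_bnd = fp_bnd)
}

#' Evaluate discharge velocity per element
#'
#' Darcy flux `v = -k grad p` at element centroids (constant per element for
#' simplicial meshes; centroid value for hexahedra).
#'
#' @param disc a [biot_discretization()].
#' @param p pressure nodal vector.
#' @return `ne x dim` matrix of velocities (m/s).
#' @export
eval_velocity <- function(disc, p) {
  mesh <- disc$mesh
  k <- disc$params$k
  ne <- nrow(mesh$elems)
  out <- matrix(NA_real_, ne, disc$dim)
  gr <- grad_at_centroid(mesh)
  pe <- matrix(p[mesh$elems], nrow = ne)
  for (c_ in seq_len(disc$dim)) {
    out[, c_] <- -k * rowSums(gr[, , c_] * pe)
  }
  out
}

# basis gradients at element centroids: ne x nn x dim
grad_at_centroid <- function(mesh) {
  ne <- nrow(mesh$elems)
  if (mesh$type == "interval") {
    gr <- array(NA_real_, c(ne, 2, 1))
    gr[, 1, 1] <- -1 / mesh$h
    gr[, 2, 1] <- 1 / mesh$h
    gr
  } else if (mesh$type == "hex") {
    hb <- hex_basis(matrix(0, 1, 3))
    gr <- array(NA_real_, c(ne, 8, 3))
    for (c_ in 1:3) {
      gr[, , c_] <- matrix(hb$dphi[1, , c_] * (2 / mesh$h[c_]),
                           ne, 8, byrow = TRUE)
    }
    gr
  } else {
    ops <- local_ops(mesh)
    ops$grads
  }
}

#' Evaluate total stress per element
#'
#' Total stress `T = 2 mu E(u) + lambda (div u) I - p I` at element
#' centroids. In 1D returns the axial stress `H_A du/dx - p`.
#'
#' @param disc a [biot_discretization()].
#' @param u displacement dof vector (components stacked).
#' @param p pressure nodal vector.
#' @return For 3D meshes an `ne x 3 x 3` array; for 1D a length-`ne` vector.
#' @export
eval_stress <- function(disc, u, p) {
  mesh <- disc$mesh
  ne <- nrow(mesh$elems)
  N <- disc$N
  gr <- grad_at_centroid(mesh)
  nn <- ncol(mesh$elems)
  pm <- rowMeans(matrix(p[mesh$elems], nrow = ne))
  if (disc$dim == 1) {
    dudx <- rowSums(gr[, , 1] * matrix(u[mesh$elems], nrow = ne))
    return(disc$params$H_A * dudx - pm)
  }
  lam <- disc$params$lambda_e; mu <- disc$params$mu_e
  Tarr <- array(0, c(ne, 3, 3))
  gradu <- array(NA_real_, c(ne, 3, 3))  # gradu[e, i, j] = d u_i / d x_j
  for (i in 1:3) {
    ui <- matrix(u[(i - 1) * N + mesh$elems], nrow = ne)
    for (j in 1:3) gradu[, i, j] <- rowSums(gr[, , j] * ui)
  }
  divu <- gradu[, 1, 1] + gradu[, 2, 2] + gradu[, 3, 3]
  for (i in 1:3) {
    for (j in 1:3) {
      Tarr[, i, j] <- mu * (gradu[, i, j] + gradu[, j, i]) +
        (i == j) * (lam * divu - pm)
    }
  }
  Tarr
}
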