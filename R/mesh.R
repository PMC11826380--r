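# Structured meshes of the box domain and reference-element utilities.
# Hexahedra use trilinear (Q1) basis functions; tetrahedra come from the
# 6-tet Kuhn split of each grid cell and use linear (P1) basis functions.
# The 1D column is a uniform interval grid with linear elements.

# VTK hexahedron local vertex signs in reference coords [-1,1]^3
hex_signs <- rbind(
  c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
  c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1)
)

# binary (ix,iy,iz) in {0,1}^3 -> VTK local index
hex_bin2loc <- function(ix, iy, iz) {
  tab <- c(`000` = 1, `100` = 2, `110` = 3, `010` = 4,
           `001` = 5, `101` = 6, `111` = 7, `011` = 8)
  tab[paste0(ix, iy, iz)]
}

# trilinear basis and reference gradients at local points (m x 3)
hex_basis <- function(xi) {
  xi <- matrix(xi, ncol = 3)
  m <- nrow(xi)
  phi <- matrix(NA_real_, m, 8)
  dphi <- array(NA_real_, c(m, 8, 3))
  for (a in 1:8) {
    s <- hex_signs[a, ]
    f1 <- (1 + s[1] * xi[, 1]) / 2
    f2 <- (1 + s[2] * xi[, 2]) / 2
    f3 <- (1 + s[3] * xi[, 3]) / 2
    phi[, a] <- f1 * f2 * f3
    dphi[, a, 1] <- s[1] / 2 * f2 * f3
    dphi[, a, 2] <- s[2] / 2 * f1 * f3
    dphi[, a, 3] <- s[3] / 2 * f1 * f2
  }
  list(phi = phi, dphi = dphi)
}

gauss1 <- 1 / sqrt(3)

hex_gauss <- function() {
  g <- gauss1
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  colnames(pts) <- NULL
  list(pts = pts, w = rep(1, 8))
}

quad_gauss <- function() {
  g <- gauss1
  pts <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  colnames(pts) <- NULL
  list(pts = pts, w = rep(1, 4))
}

# degree-2 rule on the reference tetrahedron (4 points)
tet_gauss <- function() {
  a <- 0.5854101966249685
  b <- 0.1381966011250105
  pts <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
  list(pts = pts, w = rep(1 / 24, 4))  # reference tet volume 1/6
}

# degree-2 rule on the reference triangle (edge midpoints)
tri_gauss <- function() {
  pts <- rbind(c(0.5, 0), c(0.5, 0.5), c(0, 0.5))
  list(pts = pts, w = rep(1 / 6, 3))  # reference triangle area 1/2
}

#' Structured mesh of the box domain
#'
#' Builds a structured grid of the box described by a [geometry_box()],
#' either as axis-aligned hexahedra with trilinear basis functions or as
#' their 6-tetrahedra (Kuhn) split with linear basis functions. Every
#' boundary facet is tagged with the label of the box side it lies on, so
#' the boundary partition of the geometry is inherited exactly.
#'
#' Trilinear hexahedra have a tensor-product (separable) basis; on problems
#' whose data depend on x only this makes the discrete solution exactly
#' one-dimensional, mirroring the continuous problem's invariance.
#'
#' @param geometry a [geometry_box()].
#' @param n number of cells per axis: scalar or length-3 integer vector
#'   `(nx, ny, nz)`, each at least 1.
#' @param type `"hex"` (default) or `"tet"`.
#' @return Object of class `poro_mesh`: nodes, element connectivity,
#'   per-side boundary facets with parent elements, and grid metadata.
#' @export
mesh_box <- function(geometry, n = c(8, 4, 4), type = c("hex", "tet")) {
  stopifnot(inherits(geometry, "poro_geometry"))
  type <- match.arg(type)
  n <- as.integer(rep(n, length.out = 3))
  if (any(n < 1)) stop("need at least one cell per axis")
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  xs <- seq(0, geometry$c_len, length.out = nx + 1)
  ys <- seq(-geometry$a / 2, geometry$a / 2, length.out = ny + 1)
  zs <- seq(-geometry$b / 2, geometry$b / 2, length.out = nz + 1)
  h <- c(diff(xs)[1], diff(ys)[1], diff(zs)[1])
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  colnames(nodes) <- NULL
  nid <- function(i, j, k) i + (j - 1) * (nx + 1) + (k - 1) * (nx + 1) * (ny + 1)

  cells <- as.matrix(expand.grid(i = 1:nx, j = 1:ny, k = 1:nz))
  hexes <- matrix(NA_integer_, nrow(cells), 8)
  for (a in 1:8) {
    s <- (hex_signs[a, ] + 1) / 2  # 0/1 offsets
    hexes[, a] <- nid(cells[, 1] + s[1], cells[, 2] + s[2], cells[, 3] + s[3])
  }

  if (type == "hex") {
    elems <- hexes
  } else {
    # Kuhn split: 6 tets per cell along the (0,0,0)-(1,1,1) diagonal
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    loc_tets <- matrix(NA_integer_, 6, 4)
    for (p in 1:6) {
      pos <- c(0, 0, 0)
      verts <- integer(4)
      verts[1] <- hex_bin2loc(0, 0, 0)
      for (s in 1:3) {
        pos[perms[p, s]] <- 1
        verts[s + 1] <- hex_bin2loc(pos[1], pos[2], pos[3])
      }
      loc_tets[p, ] <- verts
    }
    elems <- matrix(NA_integer_, 6 * nrow(hexes), 4)
    for (p in 1:6) {
      elems[seq(p, by = 6, length.out = nrow(hexes)), ] <- hexes[, loc_tets[p, ]]
    }
    # enforce positive orientation
    for (e in seq_len(nrow(elems))) {
      X <- nodes[elems[e, ], ]
      v <- det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))
      if (v < 0) elems[e, c(3, 4)] <- elems[e, c(4, 3)]
    }
  }

  # boundary facets per side, with parent element
  on_side <- function(idx, side) {
    co <- nodes[idx, , drop = FALSE]
    tol <- 1e-12 * max(geometry$c_len, geometry$a, geometry$b)
    switch(side,
      xmin = all(abs(co[, 1] - 0) < tol),
      xmax = all(abs(co[, 1] - geometry$c_len) < tol),
      ymin = all(abs(co[, 2] + geometry$a / 2) < tol),
      ymax = all(abs(co[, 2] - geometry$a / 2) < tol),
      zmin = all(abs(co[, 3] + geometry$b / 2) < tol),
      zmax = all(abs(co[, 3] - geometry$b / 2) < tol))
  }
  facet_idx <- if (type == "hex") {
    # VTK hex faces (local indices)
    rbind(c(1, 4, 8, 5), c(2, 3, 7, 6), c(1, 2, 6, 5),
          c(4, 3, 7, 8), c(1, 2, 3, 4), c(5, 6, 7, 8))
  } else {
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  }
  bfaces <- stats::setNames(vector("list", 6), box_sides)
  fl <- lapply(box_sides, function(s) list(nodes = NULL, parent = NULL))
  names(fl) <- box_sides
  for (e in seq_len(nrow(elems))) {
    en <- elems[e, ]
    for (f in seq_len(nrow(facet_idx))) {
      fn <- en[facet_idx[f, ]]
      for (s in box_sides) {
        if (on_side(fn, s)) {
          fl[[s]]$nodes <- rbind(fl[[s]]$nodes, fn)
          fl[[s]]$parent <- c(fl[[s]]$parent, e)
          break
        }
      }
    }
  }
  structure(list(dim = 3L, type = type, geometry = geometry,
                 nodes = nodes, elems = elems, n = n, h = h,
                 bfaces = fl),
            class = "poro_mesh")
}

#' Uniform 1D grid of the column (0, c)
#'
#' Linear elements on `nx` equal intervals. The endpoints inherit the
#' `xmin`/`xmax` labels of the geometry; volume and boundary terms carry the
#' cross-section factor `a*b` so the reduced model is dimensionally the 3D
#' model restricted to x-only fields.
#'
#' @param geometry a [geometry_box()].
#' @param nx number of intervals, at least 1.
#' @return Object of class `poro_mesh` with `dim = 1`.
#' @export
mesh_interval <- function(geometry, nx = 50) {
  stopifnot(inherits(geometry, "poro_geometry"))
  nx <- as.integer(nx)
  if (nx < 1) stop("need at least one interval")
  xs <- seq(0, geometry$c_len, length.out = nx + 1)
  nodes <- matrix(xs, ncol = 1)
  elems <- cbind(1:nx, 2:(nx + 1))
  fl <- list(
    xmin = list(nodes = matrix(1L, 1, 1), parent = 1L),
    xmax = list(nodes = matrix(nx + 1L, 1, 1), parent = nx)
  )
  structure(list(dim = 1L, type = "interval", geometry = geometry,
                 nodes = nodes, elems = elems, n = nx,
                 h = geometry$c_len / nx, bfaces = fl),
            class = "poro_mesh")
}

#' @export
print.poro_mesh <- function(x, ...) {
  cat("<poro_mesh>", if (x$dim == 1) "1D interval" else paste0("3D ", x$type),
      "-", nrow(x$nodes), "nodes,", nrow(x$elems), "elements\n")
  invisible(x)
}

#' Total measure of the mesh (volume or length)
#' @param mesh a `poro_mesh`.
#' @return Total volume (m^3) for 3D meshes, length (m) for 1D grids.
#' @export
mesh_volume <- function(mesh) {
  if (mesh$dim == 1) return(diff(range(mesh$nodes)))
  if (mesh$type == "hex") return(nrow(mesh$elems) * prod(mesh$h))
  v <- 0
  for (e in seq_len(nrow(mesh$elems))) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    v <- v + abs(det(cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ]))) / 6
  }
  v
}
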