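# CSV time series, legacy VTK field snapshots, run provenance.

fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write trajectory outputs to a directory
#'
#' Produces:
#' * `timeseries.csv` -- one row per step: time, interface scalars (`P`,
#'   `pi`, `Q`, interface pressure spread `p_spread = max - min`), circuit
#'   state components, energies and dissipations, written in full double
#'   precision (17 significant digits) so reruns are bitwise comparable;
#' * field snapshots every `stride` steps: legacy ASCII VTK
#'   (`fields_NNNN.vtk`, 3D runs) or CSV profiles `x, u, p, v, T`
#'   (`profile_NNNN.csv`, 1D runs);
#' * `run.json` -- scheme, variant, step size, mesh and package version.
#'
#' @param traj a `biot0d_trajectory`.
#' @param dir output directory (created if missing).
#' @param stride snapshot stride in steps; `0` disables snapshots.
#' @return The directory path, invisibly.
#' @export
write_outputs <- function(traj, dir, stride = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  problem <- traj$problem
  disc <- problem$disc
  coupled <- !is.null(problem$coupling)
  n_steps <- length(traj$times) - 1

  er <- energy_report(traj)
  spread <- rep(NA_real_, n_steps)
  if (!is.null(disc$sigma)) {
    for (n in seq_len(n_steps)) {
      tr <- traj$Pfield[disc$sigma$pnodes, n + 1]
      spread[n] <- max(tr) - min(tr)
    }
  }
  df <- data.frame(t = traj$times[-1])
  if (coupled) {
    df$P <- traj$P; df$pi <- traj$pi; df$Q <- traj$Q
    df$p_spread <- spread
    Yt <- t(traj$Y[, -1, drop = FALSE])
    colnames(Yt) <- paste0("y", seq_len(ncol(Yt)))
    df <- cbind(df, Yt)
  }
  df <- cbind(df, er[setdiff(names(er), "t")])
  chr <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE)
  utils::write.table(chr, file.path(dir, "timeseries.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)

  if (stride > 0) {
    snaps <- unique(c(seq(0, n_steps, by = stride), n_steps))
    for (n in snaps) {
      u <- traj$U[, n + 1]; p <- traj$Pfield[, n + 1]
      if (disc$dim == 3) {
        vel <- eval_velocity(disc, p)
        write_vtk_legacy(
          disc$mesh, file.path(dir, sprintf("fields_%04d.vtk", n)),
          point_vectors = list(displacement = matrix(u, ncol = 3)),
          point_scalars = list(pressure = p),
          cell_scalars = list(speed = sqrt(rowSums(vel^2))),
          title = sprintf("t=%g", traj$times[n + 1]))
      } else {
        vel <- eval_velocity(disc, p)
        Tel <- eval_stress(disc, u, p)
        xc <- rowMeans(matrix(disc$mesh$nodes[as.vector(disc$mesh$elems)],
                              ncol = 2))
        prof <- data.frame(
          x = fmt17(disc$mesh$nodes[, 1]), u = fmt17(u), p = fmt17(p))
        utils::write.table(prof,
                           file.path(dir, sprintf("profile_%04d.csv", n)),
                           sep = ",", quote = FALSE, row.names = FALSE)
        elem <- data.frame(x = fmt17(xc), v = fmt17(vel[, 1]),
                           T = fmt17(Tel))
        utils::write.table(elem,
                           file.path(dir, sprintf("elements_%04d.csv", n)),
                           sep = ",", quote = FALSE, row.names = FALSE)
      }
    }
  }
  meta <- list(scheme = traj$scheme, variant = traj$variant,
               order = traj$order, dt = traj$dt,
               n_steps = n_steps,
               mesh = list(dim = disc$dim, type = disc$mesh$type,
                           nodes = disc$N, elements = nrow(disc$mesh$elems)),
               package = as.character(utils::packageVersion("porocirc")))
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a mesh with fields as legacy ASCII VTK
#'
#' Unstructured-grid legacy VTK (readable by ParaView/VisIt): hexahedra as
#' cell type 12, tetrahedra as type 10.
#'
#' @param mesh a 3D [mesh_box()] mesh.
#' @param file output path.
#' @param point_scalars named list of length-N vectors.
#' @param point_vectors named list of N x 3 matrices.
#' @param cell_scalars named list of length-ne vectors.
#' @param title dataset title line.
#' @return `file`, invisibly.
#' @export
write_vtk_legacy <- function(mesh, file, point_scalars = list(),
                             point_vectors = list(), cell_scalars = list(),
                             title = "porocirc fields") {
  stopifnot(mesh$dim == 3)
  N <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  nn <- ncol(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(title)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", N, " double")
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(formatC(r, format = "g", digits = 12), collapse = " ")), con)
  wl("CELLS ", ne, " ", ne * (nn + 1))
  writeLines(apply(mesh$elems, 1, function(r)
    paste(c(nn, r - 1L), collapse = " ")), con)
  wl("CELL_TYPES ", ne)
  writeLines(rep(if (nn == 8) "12" else "10", ne), con)
  if (length(point_scalars) || length(point_vectors)) {
    wl("POINT_DATA ", N)
    for (nm in names(point_scalars)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(formatC(point_scalars[[nm]], format = "g", digits = 12), con)
    }
    for (nm in names(point_vectors)) {
      wl("VECTORS ", nm, " double")
      writeLines(apply(point_vectors[[nm]], 1, function(r)
        paste(formatC(r, format = "g", digits = 12), collapse = " ")), con)
    }
  }
  if (length(cell_scalars)) {
    wl("CELL_DATA ", ne)
    for (nm in names(cell_scalars)) {
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(formatC(cell_scalars[[nm]], format = "g", digits = 12), con)
    }
  }
  invisible(file)
}
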