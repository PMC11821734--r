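fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Export a mesh or ring solution to legacy ASCII VTK
#'
#' Writes an unstructured-grid file of quadratic hexahedra (VTK cell type
#' 25) readable by standard viewers. For a \code{ring_solution} the nodal
#' displacement vector and the per-element relative volume J, current FCD,
#' Donnan pressure, mural domain and layer tag are included.
#'
#' @param x A \code{quarter_ring_mesh} or \code{ring_solution}.
#' @param path Output file path (conventionally \code{.vtk}).
#' @return Invisibly, \code{path}.
#' @export
export_solution <- function(x, path) {
  if (inherits(x, "ring_solution")) {
    mesh <- x$mesh
    sol <- x
  } else if (inherits(x, "quarter_ring_mesh")) {
    mesh <- x
    sol <- NULL
  } else {
    stop("x must be a quarter_ring_mesh or ring_solution")
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes)
  e <- nrow(mesh$conn)
  w("# vtk DataFile Version 3.0", "gagring quarter-ring model", "ASCII",
    "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  w(apply(mesh$nodes, 1L, function(p) paste(fmt_num(p), collapse = " ")))
  w(sprintf("CELLS %d %d", e, e * 21L))
  w(apply(mesh$conn, 1L, function(cc)
    paste(c(20L, cc - 1L), collapse = " ")))
  w(sprintf("CELL_TYPES %d", e))
  w(as.character(rep(25L, e)))
  if (!is.null(sol)) {
    w(sprintf("POINT_DATA %d", n), "VECTORS displacement double")
    w(apply(sol$u, 1L, function(p) paste(fmt_num(p), collapse = " ")))
    w(sprintf("CELL_DATA %d", e))
    scalars <- list(J = sol$elem_J, cF = sol$elem_cF, pi = sol$elem_pi,
                    domain = sol$fields$domain,
                    layer = as.integer(sol$fields$layer == "media"))
    for (nm in names(scalars)) {
      w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      w(fmt_num(as.numeric(scalars[[nm]])))
    }
  }
  invisible(path)
}

#' Read back a legacy ASCII VTK file written by [export_solution()]
#'
#' @param path VTK file path.
#' @return List with \code{points}, \code{conn} (1-based, E x 20),
#'   \code{displacement} (if present), and a list of per-cell scalar fields.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  i_pts <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i_pts], " ")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(i_pts + 1):(i_pts + n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  i_cells <- grep("^CELLS", lines)[1]
  e <- as.integer(strsplit(lines[i_cells], " ")[[1]][2])
  conn <- do.call(rbind, lapply(lines[(i_cells + 1):(i_cells + e)],
                                function(l) {
    v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    v[-1] + 1L
  }))
  out <- list(points = pts, conn = conn, cell_data = list())
  i_disp <- grep("^VECTORS displacement", lines)
  if (length(i_disp)) {
    out$displacement <- do.call(rbind,
      lapply(lines[(i_disp + 1):(i_disp + n)], function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  }
  i_sc <- grep("^SCALARS ", lines)
  for (i in i_sc) {
    nm <- strsplit(lines[i], " ")[[1]][2]
    out$cell_data[[nm]] <- as.numeric(lines[(i + 2):(i + 1 + e)])
  }
  out
}
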