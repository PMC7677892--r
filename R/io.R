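# Mesh, fiber and result I/O: the plain-text triplet dialect
# (.pts/.elem/.lon), a legacy-ASCII VTK writer for visualization, penalty
# map JSON, and CSV export of simulation results.

#' Write a mesh in the plain-text triplet dialect
#'
#' `<prefix>.pts`: one "x y z" line per node; `<prefix>.elem`: one
#' "Tt n1 n2 n3 n4 region" line per tetrahedron (0-based indices);
#' optionally `<prefix>.lon`: "fx fy fz sx sy sz" per element.
#'
#' @param mesh a `tet_mesh`.
#' @param prefix output path prefix.
#' @param fibers optional `fiber_field` for the `.lon` file.
#' @return the prefix, invisibly.
#' @export
write_mesh_txt <- function(mesh, prefix, fibers = NULL) {
  pts <- file.path(paste0(prefix, ".pts"))
  writeLines(c(sprintf("%d", nrow(mesh$nodes)),
               sprintf("%.8g %.8g %.8g", mesh$nodes[, 1], mesh$nodes[, 2],
                       mesh$nodes[, 3])), pts)
  el <- file.path(paste0(prefix, ".elem"))
  writeLines(c(sprintf("%d", nrow(mesh$tets)),
               sprintf("Tt %d %d %d %d %s", mesh$tets[, 1] - 1L,
                       mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                       mesh$tets[, 4] - 1L, mesh$tet_region)), el)
  if (!is.null(fibers)) {
    writeLines(sprintf("%.8g %.8g %.8g %.8g %.8g %.8g",
                       fibers$f[, 1], fibers$f[, 2], fibers$f[, 3],
                       fibers$s[, 1], fibers$s[, 2], fibers$s[, 3]),
               file.path(paste0(prefix, ".lon")))
  }
  invisible(prefix)
}

#' Read a mesh written by [write_mesh_txt()]
#'
#' Rebuilds boundary triangles and labels geometrically where possible;
#' region labels come from the `.elem` file. Fiber directions are returned
#' when a `.lon` file is present.
#'
#' @param prefix path prefix of the `.pts`/`.elem`(/`.lon`) files.
#' @return list with `mesh` (a `tet_mesh` without surface labels beyond
#'   boundary extraction) and optionally `fibers`.
#' @export
read_mesh_txt <- function(prefix) {
  pts <- readLines(paste0(prefix, ".pts"))
  n <- as.integer(pts[1])
  nodes <- do.call(rbind, lapply(strsplit(pts[2:(n + 1)], " +"), as.numeric))
  el <- readLines(paste0(prefix, ".elem"))
  ne <- as.integer(el[1])
  parts <- strsplit(el[2:(ne + 1)], " +")
  tets <- t(vapply(parts, function(p) as.integer(p[2:5]), integer(4))) + 1L
  region <- vapply(parts, function(p) p[6], "")
  bt <- extract_boundary(tets, nodes)
  mesh <- structure(list(nodes = nodes, tets = tets, tet_region = region,
                         boundary_tris = bt,
                         boundary_label = rep("EPI", nrow(bt)),
                         apex_patch = integer(0),
                         node_flags = matrix(FALSE, n, 0),
                         long_axis = c(0, 0, 1), z_base = max(nodes[, 3]),
                         params = list()), class = "tet_mesh")
  out <- list(mesh = mesh)
  lon <- paste0(prefix, ".lon")
  if (file.exists(lon)) {
    lf <- do.call(rbind, lapply(strsplit(readLines(lon), " +"), as.numeric))
    f <- lf[, 1:3, drop = FALSE]; s <- lf[, 4:6, drop = FALSE]
    s <- vec3_normalize(s - rowSums(s * f) * f)
    f <- vec3_normalize(f)
    nn <- vec3_cross(f, s)
    R <- matrix(0, nrow(f), 9)
    R[, M3_IDX[, 1]] <- f; R[, M3_IDX[, 2]] <- s; R[, M3_IDX[, 3]] <- nn
    out$fibers <- structure(list(f = f, s = s, n = nn, R = R, angles = NULL),
                            class = "fiber_field")
  }
  out
}

#' Write a legacy-ASCII VTK unstructured grid
#'
#' Text-only VTK writer for visualization: tetrahedral cells with optional
#' point data (named numeric vectors/matrices over nodes) and cell data.
#'
#' @param mesh a `tet_mesh`.
#' @param file output path (`.vtk`).
#' @param point_data,cell_data named lists of numeric vectors (scalars) or
#'   3-column matrices (vectors).
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "cardiomech mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.8g %.8g %.8g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(c(sprintf("CELL_TYPES %d", ne),
               rep("10", ne)), con)
  wr_data <- function(dat, nn) {
    for (nm in names(dat)) {
      v <- dat[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        v <- as.numeric(v)
        v[!is.finite(v)] <- -1
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.8g", v), con)
      }
    }
  }
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    wr_data(point_data, n)
  }
  if (length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    wr_data(cell_data, ne)
  }
  invisible(file)
}

#' Serialize a penalty map to JSON
#' @param map a `penalty_map`.
#' @param file output path.
#' @param n_knots number of xi knots sampled for the stored interpolant.
#' @export
write_penalty_map <- function(map, file, n_knots = 41) {
  xi <- seq(0, 1, length.out = n_knots)
  jsonlite::write_json(list(xi_knots = xi, scale_values = map$scale(xi),
                            k_max = map$k_max,
                            bin_centers = map$bin_centers,
                            bin_means = map$bin_means),
                       file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a penalty map from JSON
#' @param file path written by [write_penalty_map()].
#' @return a `penalty_map` (linear interpolation over the stored knots).
#' @export
read_penalty_map <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  fun <- stats::approxfun(j$xi_knots, j$scale_values, rule = 2)
  structure(list(scale = function(x) clamp(fun(clamp(x, 0, 1)), 0, 1),
                 k_max = j$k_max, bin_centers = j$bin_centers,
                 bin_means = j$bin_means, bin_norm = numeric(0),
                 iso_fit = numeric(0), n_bins = length(j$bin_centers)),
            class = "penalty_map")
}

#' Export the per-step hemodynamics of a run as CSV
#' @param sim a `sim_result`.
#' @param file output path.
#' @export
write_pv_csv <- function(sim, file) {
  utils::write.csv(sim$timeline, file, row.names = FALSE)
  invisible(file)
}
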