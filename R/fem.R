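# P1 tetrahedral FEM primitives shared by the Laplace coordinate solves and
# the mechanics assembly.

# Per-tet reference shape-function gradients and volumes.
# Returns grads[[a]] (ntet x 3) for local node a = 1..4, and vol (mm^3).
#' @noRd
tet_shape_data <- function(mesh) {
  x1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  d1 <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - x1
  d2 <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - x1
  d3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - x1
  Dm <- matrix(0, nrow(d1), 9)
  Dm[, M3_IDX[, 1]] <- d1
  Dm[, M3_IDX[, 2]] <- d2
  Dm[, M3_IDX[, 3]] <- d3
  det <- m3_det(Dm)
  inv <- m3_inv(Dm, det)
  g2 <- inv[, M3_IDX[1, ], drop = FALSE]
  g3 <- inv[, M3_IDX[2, ], drop = FALSE]
  g4 <- inv[, M3_IDX[3, ], drop = FALSE]
  list(grads = list(-(g2 + g3 + g4), g2, g3, g4), vol = det / 6, Dm = Dm)
}

# Assemble the P1 stiffness matrix of -div(grad u) over the whole mesh.
#' @noRd
fem_stiffness <- function(mesh, sd = tet_shape_data(mesh)) {
  nt <- nrow(mesh$tets)
  ii <- jj <- integer(16 * nt); xx <- numeric(16 * nt)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- pos + seq_len(nt)
    ii[idx] <- mesh$tets[, a]
    jj[idx] <- mesh$tets[, b]
    xx[idx] <- sd$vol * rowSums(sd$grads[[a]] * sd$grads[[b]])
    pos <- pos + nt
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(mesh$nodes), nrow(mesh$nodes)))
}

#' Solve a Laplace problem on the mesh with Dirichlet data
#'
#' Piecewise-linear finite-element solution of the Laplace equation, used to
#' construct apico-basal and transmural wall coordinates.
#'
#' @param mesh a `tet_mesh`.
#' @param dirichlet_nodes integer node ids carrying Dirichlet values.
#' @param dirichlet_values numeric values (recycled against the node set).
#' @return numeric vector over all nodes.
#' @export
solve_laplace <- function(mesh, dirichlet_nodes, dirichlet_values) {
  n <- nrow(mesh$nodes)
  if (length(dirichlet_nodes) == 0) stop("empty Dirichlet set")
  vals <- rep_len(dirichlet_values, length(dirichlet_nodes))
  K <- fem_stiffness(mesh)
  fixed <- rep(FALSE, n); fixed[dirichlet_nodes] <- TRUE
  u <- numeric(n); u[dirichlet_nodes] <- vals
  free <- which(!fixed)
  if (length(free) > 0) {
    rhs <- -K[free, fixed, drop = FALSE] %*% u[fixed]
    u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  }
  # connectivity check: an unreachable free component yields a singular block
  if (any(!is.finite(u))) stop("disconnected Dirichlet boundary sets")
  u
}

#' Apico-basal and transmural wall coordinates
#'
#' Harmonic coordinates from Laplace solves: `xi` is 0 on the apical node
#' patch and 1 on the basal boundary (truncation plane and above); `tau` is 0
#' on the endocardial surfaces and 1 on the epicardial surfaces. Both lie in
#' `[0, 1]` by the discrete maximum principle (values are clipped for
#' round-off only).
#'
#' @param mesh a `tet_mesh` from [build_idealized_biventricle()].
#' @return object of class `wall_coords` with numeric fields `xi`, `tau`.
#' @export
compute_wall_coordinates <- function(mesh) {
  fl <- mesh$node_flags
  if (ncol(fl) == 0) stop("mesh carries no surface flags")
  basal <- which(mesh$nodes[, 3] >= mesh$z_base - 1e-9)
  if (length(mesh$apex_patch) == 0 || length(basal) == 0)
    stop("apex patch or basal boundary missing")
  xi <- solve_laplace(mesh, c(mesh$apex_patch, basal),
                      c(rep(0, length(mesh$apex_patch)), rep(1, length(basal))))
  endo <- which((fl[, "lv_endo"] | fl[, "rv_endo"]) & !fl[, "lv_epi"])
  epi <- which(fl[, "lv_epi"] | fl[, "rv_outer"])
  tau <- solve_laplace(mesh, c(endo, epi),
                       c(rep(0, length(endo)), rep(1, length(epi))))
  structure(list(xi = clamp(xi, 0, 1), tau = clamp(tau, 0, 1)),
            class = "wall_coords")
}

#' @export
print.wall_coords <- function(x, ...) {
  cat("wall_coords: xi in [", min(x$xi), ",", max(x$xi), "], tau in [",
      min(x$tau), ",", max(x$tau), "]\n")
  invisible(x)
}
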