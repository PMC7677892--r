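#' Rule-based myofiber triads
#'
#' Assigns an orthonormal fiber/sheet/normal triad to every ventricular
#' element. The transmural direction is the normalized gradient of the
#' transmural coordinate `tau`; the circumferential direction is its cross
#' product with the long axis. The helix (fiber) angle rotates linearly in
#' `tau` from `alpha_endo` on the endocardium to `alpha_epi` on the
#' epicardium, and the sheet angle likewise from `beta_endo` to `beta_epi`.
#' Defaults are the standard ventricular rule: fiber angle 80 deg (endo) to
#' -60 deg (epi), sheet angle -65 deg to 25 deg.
#'
#' Elements with a vanishing transmural gradient (or a transmural direction
#' parallel to the long axis, as at the apical pole) fall back to the average
#' triad of node-adjacent elements; the number of such elements is reported
#' via `message()`.
#'
#' @param mesh a `tet_mesh`.
#' @param coords a [compute_wall_coordinates()] result.
#' @param alpha_endo,alpha_epi helix angles on endo/epicardium (degrees).
#' @param beta_endo,beta_epi sheet angles on endo/epicardium (degrees).
#' @return object of class `fiber_field`: matrices `f`, `s`, `n` (ntet x 3)
#'   and the rotation `R = [f s n]` stored row-major (ntet x 9).
#' @export
assign_rule_based_fibers <- function(mesh, coords, alpha_endo = 80,
                                     alpha_epi = -60, beta_endo = -65,
                                     beta_epi = 25) {
  sd <- tet_shape_data(mesh)
  tau_e <- element_mean(mesh, coords$tau)
  # per-element gradient of tau
  gt <- sd$grads[[1]] * coords$tau[mesh$tets[, 1]] +
    sd$grads[[2]] * coords$tau[mesh$tets[, 2]] +
    sd$grads[[3]] * coords$tau[mesh$tets[, 3]] +
    sd$grads[[4]] * coords$tau[mesh$tets[, 4]]
  gnorm <- vec3_norm(gt)
  la <- matrix(mesh$long_axis, nrow(gt), 3, byrow = TRUE)
  t_hat <- gt / pmax(gnorm, 1e-300)
  c_raw <- vec3_cross(la, t_hat)
  cnorm <- vec3_norm(c_raw)
  bad <- gnorm < 1e-8 | cnorm < 1e-3
  t_hat[bad, ] <- 0; c_raw[bad, ] <- 0
  c_hat <- c_raw / pmax(cnorm, 1e-300)
  l_hat <- vec3_cross(t_hat, c_hat)

  deg <- pi / 180
  al <- (alpha_endo + tau_e * (alpha_epi - alpha_endo)) * deg
  be <- (beta_endo + tau_e * (beta_epi - beta_endo)) * deg
  f <- cos(al) * c_hat + sin(al) * l_hat
  s <- cos(be) * t_hat + sin(be) * vec3_cross(f, t_hat)

  if (any(bad)) {
    f_fix <- f; s_fix <- s
    remaining <- which(bad)
    # node-adjacency averaging, repeated until all degenerate elements filled
    for (pass in 1:20) {
      if (length(remaining) == 0) break
      good <- setdiff(seq_len(nrow(f)), remaining)
      node_f <- node_average_from_elements(mesh, f_fix, good)
      node_s <- node_average_from_elements(mesh, s_fix, good)
      fe <- element_mean_mat(mesh, node_f, remaining)
      se <- element_mean_mat(mesh, node_s, remaining)
      ok <- vec3_norm(fe) > 1e-6
      f_fix[remaining[ok], ] <- fe[ok, , drop = FALSE]
      s_fix[remaining[ok], ] <- se[ok, , drop = FALSE]
      remaining <- remaining[!ok]
    }
    message(sum(bad), " elements with degenerate transmural gradient; ",
            "triads filled from neighbours")
    f <- f_fix; s <- s_fix
  }

  # Gram-Schmidt clean-up to strict orthonormality
  f <- vec3_normalize(f)
  s <- vec3_normalize(s - rowSums(s * f) * f)
  n <- vec3_cross(f, s)
  R <- matrix(0, nrow(f), 9)
  R[, M3_IDX[, 1]] <- f
  R[, M3_IDX[, 2]] <- s
  R[, M3_IDX[, 3]] <- n
  structure(list(f = f, s = s, n = n, R = R,
                 angles = c(alpha_endo = alpha_endo, alpha_epi = alpha_epi,
                            beta_endo = beta_endo, beta_epi = beta_epi)),
            class = "fiber_field")
}

#' Uniform fiber field (validation helper)
#'
#' Constant triad on every element, for bar-mesh and material-point tests.
#' @param mesh a `tet_mesh`.
#' @param f,s fiber and sheet directions (3-vectors, need not be unit).
#' @return a `fiber_field`.
#' @export
uniform_fiber_field <- function(mesh, f = c(1, 0, 0), s = c(0, 1, 0)) {
  nt <- nrow(mesh$tets)
  f <- f / sqrt(sum(f^2))
  s <- s - sum(s * f) * f; s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])
  fm <- matrix(f, nt, 3, byrow = TRUE)
  sm <- matrix(s, nt, 3, byrow = TRUE)
  nm <- matrix(n, nt, 3, byrow = TRUE)
  R <- matrix(0, nt, 9)
  R[, M3_IDX[, 1]] <- fm; R[, M3_IDX[, 2]] <- sm; R[, M3_IDX[, 3]] <- nm
  structure(list(f = fm, s = sm, n = nm, R = R, angles = NULL),
            class = "fiber_field")
}

#' Helix angle of a fiber field
#'
#' Signed angle (degrees) of the fiber direction within the local tangent
#' plane, measured from the circumferential direction toward the apico-basal
#' tangent; used to verify the linear transmural rotation rule.
#' @param mesh a `tet_mesh`.
#' @param coords a `wall_coords`.
#' @param fibers a `fiber_field`.
#' @return numeric vector (ntet), NA for degenerate elements.
#' @export
fiber_helix_angle <- function(mesh, coords, fibers) {
  sd <- tet_shape_data(mesh)
  gt <- sd$grads[[1]] * coords$tau[mesh$tets[, 1]] +
    sd$grads[[2]] * coords$tau[mesh$tets[, 2]] +
    sd$grads[[3]] * coords$tau[mesh$tets[, 3]] +
    sd$grads[[4]] * coords$tau[mesh$tets[, 4]]
  t_hat <- vec3_normalize(gt)
  la <- matrix(mesh$long_axis, nrow(gt), 3, byrow = TRUE)
  c_raw <- vec3_cross(la, t_hat)
  cnorm <- vec3_norm(c_raw)
  c_hat <- c_raw / pmax(cnorm, 1e-300)
  l_hat <- vec3_cross(t_hat, c_hat)
  ang <- atan2(rowSums(fibers$f * l_hat), rowSums(fibers$f * c_hat)) * 180 / pi
  ang[cnorm < 1e-3 | vec3_norm(gt) < 1e-8] <- NA_real_
  ang
}

#' Transmural component of the fiber direction
#'
#' `|f . t_hat|` per element with `t_hat` the unit transmural direction
#' (gradient of `tau`); small values confirm fibers are tangent to the wall.
#' @param mesh a `tet_mesh`.
#' @param coords a `wall_coords`.
#' @param fibers a `fiber_field`.
#' @return numeric vector (ntet), NA where the gradient degenerates.
#' @export
fiber_transmural_component <- function(mesh, coords, fibers) {
  sd <- tet_shape_data(mesh)
  gt <- sd$grads[[1]] * coords$tau[mesh$tets[, 1]] +
    sd$grads[[2]] * coords$tau[mesh$tets[, 2]] +
    sd$grads[[3]] * coords$tau[mesh$tets[, 3]] +
    sd$grads[[4]] * coords$tau[mesh$tets[, 4]]
  gn <- vec3_norm(gt)
  out <- abs(rowSums(fibers$f * gt)) / pmax(gn, 1e-300)
  out[gn < 1e-8] <- NA_real_
  out
}

#' @noRd
element_mean <- function(mesh, nodal) {
  (nodal[mesh$tets[, 1]] + nodal[mesh$tets[, 2]] +
     nodal[mesh$tets[, 3]] + nodal[mesh$tets[, 4]]) / 4
}

#' @noRd
element_mean_mat <- function(mesh, nodal_mat, elems) {
  tt <- mesh$tets[elems, , drop = FALSE]
  (nodal_mat[tt[, 1], , drop = FALSE] + nodal_mat[tt[, 2], , drop = FALSE] +
     nodal_mat[tt[, 3], , drop = FALSE] + nodal_mat[tt[, 4], , drop = FALSE]) / 4
}

# average element vectors onto nodes, using only `elems`
#' @noRd
node_average_from_elements <- function(mesh, evec, elems) {
  tt <- mesh$tets[elems, , drop = FALSE]
  ids <- as.vector(tt)
  vals <- rbind(evec[elems, , drop = FALSE], evec[elems, , drop = FALSE],
                evec[elems, , drop = FALSE], evec[elems, , drop = FALSE])
  uid <- sort(unique(ids))
  acc <- rowsum_by(vals, match(ids, uid), length(uid))
  cnt <- tabulate(match(ids, uid), length(uid))
  out <- matrix(0, nrow(mesh$nodes), 3)
  out[uid, ] <- acc / cnt
  out
}
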