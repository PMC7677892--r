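# Anisotropic eikonal activation on the ventricular tetrahedra.
#
# The squared-velocity tensor is M = v_f^2 f f' + v_s^2 s s' + v_n^2 n n';
# travel time of a straight segment w inside an element is |w|_G with
# G = M^-1. The solver initializes with anisotropic Dijkstra on the edge
# graph (an upper bound: paths restricted to edges) and then relaxes with
# within-element updates from faces and edges until stationary, so the
# result can only improve on the graph distance.

#' Conduction parameters for the eikonal solve
#' @param v_f,v_s,v_n conduction velocities along fiber/sheet/normal (mm/ms),
#'   `v_f >= v_s >= v_n > 0`.
#' @param stim_nodes stimulus node set (defaults to the RV endocardium below
#'   `stim_xi_max` when solving on a biventricle).
#' @param qrs_target optional target total activation time (ms) for
#'   [tune_conduction()].
#' @param stim_xi_max apico-basal cutoff of the default RV stimulus set.
#' @export
conduction_params <- function(v_f = 0.6, v_s = 0.4, v_n = 0.2,
                              stim_nodes = NULL, qrs_target = NULL,
                              stim_xi_max = 0.7) {
  if (!(v_f >= v_s && v_s >= v_n && v_n > 0))
    stop("conduction velocities must satisfy v_f >= v_s >= v_n > 0")
  structure(list(v_f = v_f, v_s = v_s, v_n = v_n, stim_nodes = stim_nodes,
                 qrs_target = qrs_target, stim_xi_max = stim_xi_max),
            class = "conduction_params")
}

#' Default stimulus set: RV endocardial surface below an apico-basal cutoff
#' @param mesh a `tet_mesh`.
#' @param coords a `wall_coords`.
#' @param xi_max apico-basal cutoff.
#' @return integer node ids.
#' @export
rv_endo_stimulus <- function(mesh, coords, xi_max = 0.7) {
  tris <- mesh$boundary_tris[mesh$boundary_label == "RV_ENDO", , drop = FALSE]
  ids <- unique(as.vector(tris))
  ids[coords$xi[ids] < xi_max]
}

#' @noRd
velocity_tensors <- function(fibers, params) {
  params$v_f^2 * m3_outer(fibers$f) + params$v_s^2 * m3_outer(fibers$s) +
    params$v_n^2 * m3_outer(fibers$n)
}

#' Anisotropic Dijkstra activation times (edge-graph oracle)
#'
#' Shortest travel times on the tetrahedral edge graph, with each edge
#' weighted by its length over the directional speed `sqrt(e' M e)/|e|`,
#' taking the fastest adjacent element per edge. Serves as the upper-bound
#' oracle and the initial guess of [solve_eikonal()].
#'
#' @param mesh a `tet_mesh`.
#' @param fibers a `fiber_field`.
#' @param params a [conduction_params()] with non-empty `stim_nodes`.
#' @return numeric vector of times (ms) over all nodes; `NA` outside the
#'   ventricular regions.
#' @export
dijkstra_activation <- function(mesh, fibers, params) {
  ed <- eikonal_edges(mesh, fibers, params)
  stim <- params$stim_nodes
  if (is.null(stim) || length(stim) == 0) stop("stimulus node set is empty")
  g <- igraph::make_graph(t(ed$edges), n = nrow(mesh$nodes), directed = FALSE)
  dmat <- igraph::distances(g, v = stim, weights = ed$w)
  d <- apply(dmat, 2, min)
  vnodes <- ed$vnodes
  if (any(!is.finite(d[vnodes])))
    stop("unreachable ventricular nodes: stimulus not connected to all tissue")
  d[setdiff(seq_along(d), vnodes)] <- NA_real_
  d
}

# ventricular edge list with anisotropic weights
#' @noRd
eikonal_edges <- function(mesh, fibers, params) {
  vt <- which(mesh$tet_region %in% c("LV_MYO", "RV_MYO"))
  tets <- mesh$tets[vt, , drop = FALSE]
  M <- velocity_tensors(fibers, params)[vt, , drop = FALSE]
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e_from <- as.vector(tets[, pairs[, 1]])
  e_to <- as.vector(tets[, pairs[, 2]])
  ev <- mesh$nodes[e_to, , drop = FALSE] - mesh$nodes[e_from, , drop = FALSE]
  Grep <- m3_inv(M)[rep(seq_len(nrow(M)), 6), , drop = FALSE]
  # straight-segment (group) travel time sqrt(e' M^-1 e): edge length over
  # the directional speed along the ray
  w_inst <- sqrt(rowSums(ev * m3_mulvec(Grep, ev)))
  a <- pmin(e_from, e_to); b <- pmax(e_from, e_to)
  key <- paste(a, b)
  # fastest adjacent element defines the edge weight
  o <- order(key, w_inst)
  first <- !duplicated(key[o])
  sel <- o[first]
  list(edges = cbind(a[sel], b[sel]), w = w_inst[sel],
       vnodes = sort(unique(c(a, b))), vt = vt)
}

#' Solve the anisotropic eikonal equation
#'
#' Activation initiated at `params$stim_nodes` (time 0). Non-ventricular
#' regions are excluded from the solve and carry `NA`.
#'
#' @inheritParams dijkstra_activation
#' @param tol stationarity tolerance (ms).
#' @param max_sweeps cap on relaxation sweeps.
#' @return object of class `activation_map` with `t_act` (ms, per node) and
#'   metadata.
#' @export
solve_eikonal <- function(mesh, fibers, params, tol = 1e-3, max_sweeps = 200) {
  t0 <- dijkstra_activation(mesh, fibers, params)
  vt <- which(mesh$tet_region %in% c("LV_MYO", "RV_MYO"))
  tets <- mesh$tets[vt, , drop = FALSE]
  M <- velocity_tensors(fibers, params)[vt, , drop = FALSE]
  G <- m3_inv(M)
  nt <- nrow(tets)

  # expand (element, target-slot) rows: target node and its opposite face
  slot_face <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  tgt <- as.vector(tets[, c(1, 2, 3, 4)])
  fa <- as.vector(tets[, slot_face[, 1]])
  fb <- as.vector(tets[, slot_face[, 2]])
  fc <- as.vector(tets[, slot_face[, 3]])
  Ge <- G[rep(seq_len(nt), 4), , drop = FALSE]
  x4 <- mesh$nodes[tgt, , drop = FALSE]
  xa <- mesh$nodes[fa, , drop = FALSE]
  xb <- mesh$nodes[fb, , drop = FALSE]
  xc <- mesh$nodes[fc, , drop = FALSE]

  gdot <- function(u, v) rowSums(u * m3_mulvec(Ge, v))
  gn <- function(u) sqrt(pmax(gdot(u, u), 0))

  edge_candidate <- function(ti, tj, xi, xj) {
    # minimize over the edge interior; endpoints are covered by the vertex
    # candidates of the Dijkstra bound
    e <- xj - xi
    w0 <- x4 - xi
    A <- gdot(e, e); B <- gdot(e, w0); Cq <- gdot(w0, w0)
    dt <- tj - ti
    a2 <- A * (A - dt^2); a1 <- -2 * B * (A - dt^2); a0 <- B^2 - dt^2 * Cq
    disc <- a1^2 - 4 * a2 * a0
    best <- rep(Inf, length(A))
    for (sgn in c(-1, 1)) {
      lam <- (-a1 + sgn * sqrt(pmax(disc, 0))) / (2 * a2)
      ok <- is.finite(lam) & disc >= 0 & lam > 0 & lam < 1
      if (!any(ok)) next
      w <- w0 - lam * e
      val <- ti + lam * dt + gn(w)
      best <- pmin(best, ifelse(ok, val, Inf))
    }
    best
  }

  face_candidate <- function(t1, t2, t3) {
    e1 <- xa - xc; e2 <- xb - xc; w3 <- x4 - xc
    dt1 <- t1 - t3; dt2 <- t2 - t3
    g11 <- gdot(e1, e1); g12 <- gdot(e1, e2); g22 <- gdot(e2, e2)
    det2 <- g11 * g22 - g12^2
    aa <- (dt1 * g22 - dt2 * g12) / det2
    bb <- (dt2 * g11 - dt1 * g12) / det2
    q <- aa^2 * g11 + 2 * aa * bb * g12 + bb^2 * g22
    m <- vec3_cross(e1, e2)
    h <- m3_mulvec(m3_inv(Ge), m)           # G^-1 (e1 x e2), G-orthogonal to face
    hGh <- gdot(h, h)
    c2 <- (1 - q) / hGh
    best <- rep(Inf, length(q))
    valid0 <- is.finite(c2) & c2 > 0
    mm2 <- rowSums(m * m)
    for (sgn in c(-1, 1)) {
      cc <- sgn * sqrt(pmax(c2, 0))
      u <- aa * e1 + bb * e2 + cc * h
      um <- rowSums(u * m)
      s <- rowSums(w3 * m) / um
      r <- w3 - s * u
      lam1 <- rowSums(vec3_cross(r, e2) * m) / mm2
      lam2 <- rowSums(vec3_cross(e1, r) * m) / mm2
      ok <- valid0 & is.finite(s) & s > 0 &
        lam1 > -1e-9 & lam2 > -1e-9 & (lam1 + lam2) < 1 + 1e-9
      val <- t3 + lam1 * dt1 + lam2 * dt2 + s
      best <- pmin(best, ifelse(ok, val, Inf))
    }
    best
  }

  t_act <- t0
  ord <- order(tgt)
  tgt_o <- tgt[ord]
  first_of <- !duplicated(tgt_o)
  for (sweep in seq_len(max_sweeps)) {
    ta <- t_act[fa]; tb <- t_act[fb]; tc <- t_act[fc]
    cand <- pmin(
      edge_candidate(ta, tb, xa, xb),
      edge_candidate(tb, tc, xb, xc),
      edge_candidate(ta, tc, xa, xc),
      face_candidate(ta, tb, tc))
    cand_o <- cand[ord]
    # running min per target node: order by (node, candidate)
    o2 <- order(tgt_o, cand_o)
    node_min_val <- cand_o[o2][first_of]
    node_min_id <- tgt_o[o2][first_of]
    newt <- t_act
    upd <- pmin(newt[node_min_id], node_min_val, na.rm = FALSE)
    change <- max(newt[node_min_id] - upd, 0, na.rm = TRUE)
    newt[node_min_id] <- upd
    if (!is.null(params$stim_nodes)) newt[params$stim_nodes] <- 0
    t_act <- newt
    if (change < tol) break
  }
  structure(list(t_act = t_act, stim_nodes = params$stim_nodes,
                 params = params, sweeps = sweep,
                 dijkstra = t0), class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  tv <- x$t_act[is.finite(x$t_act)]
  cat("activation_map: total activation time", round(max(tv) - min(tv), 2),
      "ms over", length(tv), "nodes (", x$sweeps, "sweeps )\n")
  invisible(x)
}

#' Total activation time of a map
#' @param amap an `activation_map`.
#' @return max minus min finite activation time (ms).
#' @export
total_activation_time <- function(amap) {
  tv <- amap$t_act[is.finite(amap$t_act)]
  max(tv) - min(tv)
}

#' Tune conduction velocities to a target total activation time
#'
#' Eikonal times scale inversely with a uniform velocity scaling, so a
#' single rescale reaches the target exactly (up to solver stationarity).
#'
#' @param mesh,fibers,params as in [solve_eikonal()]; `params$qrs_target`
#'   must be set (ms).
#' @return updated `conduction_params`.
#' @export
tune_conduction <- function(mesh, fibers, params) {
  if (is.null(params$qrs_target) || params$qrs_target <= 0)
    stop("qrs_target must be a positive duration (ms)")
  amap <- solve_eikonal(mesh, fibers, params)
  fac <- total_activation_time(amap) / params$qrs_target
  out <- params
  out$v_f <- params$v_f * fac
  out$v_s <- params$v_s * fac
  out$v_n <- params$v_n * fac
  out
}
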