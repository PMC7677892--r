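# Motion and hemodynamic metrics: node-wise distance statistics against the
# target motion, atrioventricular plane displacement (AVPD, positive down),
# ventricular apex displacement (VAD, positive up), ejection fraction, peak
# pressure, fiber strain and wall thickening.

#' Ventricular node set of a mesh
#' @param mesh a `tet_mesh`.
#' @return integer node ids belonging to LV_MYO or RV_MYO elements.
#' @export
ventricular_nodes <- function(mesh) {
  sort(unique(as.vector(mesh$tets[mesh$tet_region %in% c("LV_MYO", "RV_MYO"), ])))
}

#' Basal-ring node set (xi = 1 rim of the ventricular wall)
#' @param mesh a `tet_mesh`.
#' @param coords a `wall_coords`.
#' @param tol xi tolerance.
#' @export
basal_ring_nodes <- function(mesh, coords, tol = 1e-6) {
  vn <- ventricular_nodes(mesh)
  vn[coords$xi[vn] >= 1 - tol]
}

#' Node-wise distance statistics between two displacement fields
#'
#' Mean and population SD of the per-node Euclidean distance between a
#' simulated and a reference (target) displacement field over a node
#' subset.
#'
#' @param u_sim,u_ref n x 3 displacement fields (mm) with matched node
#'   indexing.
#' @param nodes node subset (default: all rows).
#' @return named vector `c(mean, sd)` in mm.
#' @export
node_distance_stats <- function(u_sim, u_ref, nodes = seq_len(nrow(u_sim))) {
  if (!all(dim(u_sim) == dim(u_ref)))
    stop("mismatched displacement field dimensions")
  d <- vec3_norm(u_sim[nodes, , drop = FALSE] - u_ref[nodes, , drop = FALSE])
  c(mean = mean(d), sd = sqrt(mean((d - mean(d))^2)))
}

#' Atrioventricular plane displacement (positive down)
#'
#' `AVPD = -mean(u . long_axis)` over the basal ring: positive when the
#' base moves toward the apex.
#' @param u n x 3 displacement (mm).
#' @param ring basal ring node ids.
#' @param long_axis unit vector pointing apex -> base.
#' @export
avpd <- function(u, ring, long_axis = c(0, 0, 1)) {
  if (length(ring) == 0) stop("empty basal ring")
  -mean(u[ring, , drop = FALSE] %*% long_axis)
}

#' Ventricular apex displacement (positive up)
#'
#' `VAD = +mean(u . long_axis)` over the apex patch: positive when the apex
#' moves toward the base.
#' @param u n x 3 displacement (mm).
#' @param apex apex node ids.
#' @param long_axis unit vector pointing apex -> base.
#' @export
vad <- function(u, apex, long_axis = c(0, 0, 1)) {
  if (length(apex) == 0) stop("empty apex set")
  mean(u[apex, , drop = FALSE] %*% long_axis)
}

#' Ejection fraction and peak pressure from a beat
#' @param sim a `sim_result`.
#' @param cavity `"LV"` or `"RV"`.
#' @return named vector: `EF` (%), `PP` (kPa), `V_ED`, `V_ES` (mL).
#' @export
ejection_metrics <- function(sim, cavity = "LV") {
  tl <- sim$timeline
  V <- tl[[paste0("V_", cavity)]]
  p <- tl[[paste0("p_", cavity)]]
  V_ed <- sim$V_ed[[cavity]]
  V_es <- min(V)
  c(EF = 100 * (V_ed - V_es) / V_ed, PP = max(p), V_ED = V_ed, V_ES = V_es)
}

#' Per-element fiber strain E_ff
#'
#' Green-Lagrange strain along the fiber direction computed from the
#' element deformation gradients of a displacement field.
#' @param mesh a `tet_mesh`.
#' @param fibers a `fiber_field`.
#' @param u n x 3 displacement (mm).
#' @return numeric vector (ntet).
#' @export
fiber_strain_field <- function(mesh, fibers, u) {
  sd <- tet_shape_data(mesh)
  nt <- nrow(mesh$tets)
  Fm <- m3_identity(nt)
  for (a in 1:4) {
    ua <- u[mesh$tets[, a], , drop = FALSE]
    for (i in 1:3) for (j in 1:3)
      Fm[, M3_IDX[i, j]] <- Fm[, M3_IDX[i, j]] + ua[, i] * sd$grads[[a]][, j]
  }
  Cm <- m3_mul(m3_t(Fm), Fm)
  Em <- Cm / 2
  Em[, c(1, 5, 9)] <- Em[, c(1, 5, 9)] - 0.5
  rowSums(fibers$f * m3_mulvec(Em, fibers$f))
}

#' Transmural wall thickening
#'
#' Pairs each ventricular epicardial node with the nearest endocardial node
#' along the inward reference normal and reports the percent change of the
#' pair distance under a displacement field.
#'
#' @param mesh a `tet_mesh`.
#' @param u n x 3 displacement (mm).
#' @param max_angle_cos minimum cosine between the pair direction and the
#'   inward normal for a valid pair.
#' @return data.frame with `epi`, `endo` node ids, `t_ed`, `t_es` (mm) and
#'   `thickening_pct`.
#' @export
wall_thickening <- function(mesh, u, max_angle_cos = 0.8) {
  sw <- surface_node_weights(mesh, "EPI")
  vn <- ventricular_nodes(mesh)
  epi <- intersect(sw$nodes, vn)
  nrm <- sw$normal[match(epi, sw$nodes), , drop = FALSE]
  endo_ids <- intersect(unique(as.vector(
    mesh$boundary_tris[mesh$boundary_label %in% c("LV_ENDO", "RV_ENDO"), ])), vn)
  ex <- mesh$nodes[endo_ids, , drop = FALSE]
  out <- vector("list", length(epi))
  for (i in seq_along(epi)) {
    xp <- mesh$nodes[epi[i], ]
    dvec <- t(t(ex) - xp)               # endo - epi
    dist <- sqrt(rowSums(dvec^2))
    cosang <- -(dvec %*% nrm[i, ]) / pmax(dist, 1e-12)
    ok <- which(cosang > max_angle_cos)
    if (length(ok) == 0) next
    j <- ok[which.min(dist[ok])]
    t_ed <- dist[j]
    pe <- xp + u[epi[i], ]
    pn <- ex[j, ] + u[endo_ids[j], ]
    t_es <- sqrt(sum((pe - pn)^2))
    out[[i]] <- data.frame(epi = epi[i], endo = endo_ids[j], t_ed = t_ed,
                           t_es = t_es,
                           thickening_pct = 100 * (t_es - t_ed) / t_ed)
  }
  do.call(rbind, out)
}

#' Mean epicardial normal displacement binned by apico-basal position
#' @param mesh a `tet_mesh`.
#' @param coords a `wall_coords`.
#' @param u displacement field (mm), or list of fields (maximum |u.n0| over
#'   them, as in [extract_epicardial_normal_displacement()]).
#' @param n_bins number of xi bins.
#' @return data.frame with `xi` (bin centers) and `disp` (mm).
#' @export
epi_normal_profile <- function(mesh, coords, u, n_bins = 10) {
  if (is.matrix(u)) u <- list(u)
  ext <- extract_epicardial_normal_displacement(mesh, u)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- clamp(findInterval(coords$xi[ext$nodes], edges,
                            rightmost.closed = TRUE), 1, n_bins)
  data.frame(
    xi = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    disp = as.numeric(tapply(ext$value, factor(bin, levels = seq_len(n_bins)),
                             mean)))
}

#' Phase-aligned motion comparison of a run against the target
#'
#' Computes node-distance statistics at the onset and end of LV ejection,
#' matching the target by fraction of systole elapsed (ED -> peak frame),
#' plus AVPD/VAD during IVC and ejection and the mean epicardial normal
#' displacement of the free wall during IVC.
#'
#' @param sim a `sim_result`.
#' @param shared the [build_shared()] inputs used for the run.
#' @return list of metrics.
#' @export
motion_metrics <- function(sim, shared) {
  mesh <- shared$mesh; coords <- shared$coords
  vn <- ventricular_nodes(mesh)
  ring <- basal_ring_nodes(mesh, coords)
  apex <- mesh$apex_patch
  la <- mesh$long_axis
  ev <- sim$events
  need <- c("lv_ivc_start", "lv_ejection_onset", "lv_ejection_end")
  if (!all(need %in% names(ev)))
    stop("run did not complete LV ejection; phases reached: ",
         paste(unique(sim$timeline$phase_LV), collapse = ", "))
  t0 <- ev[["lv_ivc_start"]]; t_on <- ev[["lv_ejection_onset"]]
  t_es <- ev[["lv_ejection_end"]]
  frac_on <- (t_on - t0) / (t_es - t0)

  u_on <- displacement_at(sim, "lv_ejection_onset")
  u_es <- displacement_at(sim, "lv_ejection_end")
  tgt_on <- target_at_fraction(shared$motion, frac_on)
  tgt_es <- target_at_fraction(shared$motion, 1)

  # IVC window: free-wall (non-septal) epicardial outward normal motion
  k_ivc <- which(sim$time >= t0 & sim$time < t_on)
  sw <- surface_node_weights(mesh, "EPI")
  fw <- sw$nodes %in% vn
  ivc_out <- 0
  vad_ivc <- 0
  if (length(k_ivc) > 0) {
    outw <- numeric(sum(fw))
    vads <- numeric(length(k_ivc))
    for (i in seq_along(k_ivc)) {
      uu <- displacement_at(sim, k_ivc[i])
      outw <- pmax(outw, rowSums(uu[sw$nodes[fw], , drop = FALSE] *
                                   sw$normal[fw, , drop = FALSE]))
      vads[i] <- vad(uu, apex, la)
    }
    ivc_out <- mean(pmax(outw, 0))
    vad_ivc <- max(vads)
  }

  list(
    dist_onset = node_distance_stats(u_on, tgt_on, vn),
    dist_es = node_distance_stats(u_es, tgt_es, vn),
    avpd_ivc = avpd(u_on, ring, la),
    avpd_ejection = avpd(u_es, ring, la),
    vad_ivc = vad_ivc,
    vad_ejection = vad(u_es, apex, la),
    ivc_epi_outward = ivc_out,
    ef = ejection_metrics(sim, "LV"),
    frac_onset = frac_on)
}
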