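#' Geometry parameters for the idealized biventricle
#'
#' Parametric stand-in for a patient four-chamber anatomy: a truncated
#' half-ellipsoid LV, a crescent-shaped RV free wall attached to the LV
#' epicardium, and a thin basal tissue band above the truncation plane whose
#' upper rim anchors the omni-directional vein springs.
#'
#' @param lv_length LV endocardial apex-to-base length along the long axis (mm).
#' @param lv_radius LV endocardial equatorial radius (mm).
#' @param lv_thickness LV wall thickness (mm).
#' @param rv_gap maximum RV cavity width between septum and free wall (mm).
#' @param rv_thickness RV free-wall thickness (mm).
#' @param rv_span angular span of the RV attachment on the LV free wall (rad).
#' @param rv_apex_frac apico-basal position (0..1) where the RV cavity begins.
#' @param trunc_height height of the basal truncation plane above the
#'   ellipsoid equator (mm).
#' @param band_height height of the basal tissue band above the truncation
#'   plane (mm).
#' @param vein_count number of cropped-vein anchor patches on the upper rim
#'   of the basal band (omni-directional springs act only there).
#' @param vein_radius radius of each vein anchor patch (mm).
#' @param edge_length target tetrahedral edge length (mm). The default is the
#'   desk-scale resolution used throughout; production-grade meshes in this
#'   field are ~1 mm.
#' @param apex_radius radius of the apical node patch used as the Dirichlet
#'   set of the apico-basal Laplace problem (mm).
#' @return object of class `geometry_params`.
#' @export
geometry_params <- function(lv_length = 80, lv_radius = 25, lv_thickness = 9,
                            rv_gap = 16, rv_thickness = 5,
                            rv_span = 0.85 * pi, rv_apex_frac = 0.35,
                            trunc_height = 15, band_height = 10,
                            edge_length = 8, apex_radius = NULL,
                            vein_count = 3, vein_radius = 12) {
  if (is.null(apex_radius)) apex_radius <- max(5, 1.2 * edge_length)
  p <- list(lv_length = lv_length, lv_radius = lv_radius,
            lv_thickness = lv_thickness, rv_gap = rv_gap,
            rv_thickness = rv_thickness, rv_span = rv_span,
            rv_apex_frac = rv_apex_frac, trunc_height = trunc_height,
            band_height = band_height, edge_length = edge_length,
            apex_radius = apex_radius, vein_count = vein_count,
            vein_radius = vein_radius)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals[names(vals) != "rv_apex_frac"] <= 0))
    stop("all geometry parameters must be positive and finite")
  if (lv_thickness >= lv_radius)
    stop("degenerate geometry: wall thickness must be smaller than the radius")
  if (trunc_height >= lv_length)
    stop("degenerate geometry: truncation height must be below lv_length")
  class(p) <- "geometry_params"
  p
}

# ---- generic hex grid -> tetrahedra -------------------------------------

# Decompose hexahedral cells (n x 8 global ids, VTK-like vertex order
# (000,100,110,010,001,101,111,011)) into tetrahedra by coning face fans to
# the lowest-id vertex of each cell. Face fans depend only on the face's own
# vertex ids, so shared faces are triangulated identically in both cells and
# the decomposition is conforming. Degenerate (collapsed) cells shed
# zero-volume tets, which handles polar wedges for free.
#' @noRd
hexes_to_tets <- function(hex, nodes) {
  faces_local <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                       c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  n <- nrow(hex)
  v0 <- hex[cbind(seq_len(n), max.col(-hex, ties.method = "first"))]
  tets <- vector("list", 6L)
  for (fi in 1:6) {
    f <- hex[, faces_local[fi, ], drop = FALSE]
    has_v0 <- (f[, 1] == v0) | (f[, 2] == v0) | (f[, 3] == v0) | (f[, 4] == v0)
    k <- max.col(-f, ties.method = "first")
    idx <- function(off) f[cbind(seq_len(n), ((k - 1 + off) %% 4) + 1)]
    a <- idx(0); b <- idx(1); c_ <- idx(2); d <- idx(3)
    t1 <- cbind(v0, a, b, c_)
    t2 <- cbind(v0, a, c_, d)
    keep <- !has_v0
    tets[[fi]] <- rbind(t1[keep, , drop = FALSE], t2[keep, , drop = FALSE])
  }
  tt <- do.call(rbind, tets)
  # drop tets with repeated vertices (degenerate faces of collapsed cells)
  dup <- (tt[, 1] == tt[, 2]) | (tt[, 1] == tt[, 3]) | (tt[, 1] == tt[, 4]) |
    (tt[, 2] == tt[, 3]) | (tt[, 2] == tt[, 4]) | (tt[, 3] == tt[, 4])
  tt <- tt[!dup, , drop = FALSE]
  dimnames(tt) <- NULL
  v6 <- tet_signed_volume6(tt, nodes)
  flip <- v6 < 0
  if (any(flip)) tt[flip, c(3, 4)] <- tt[flip, c(4, 3)]
  scale3 <- max(abs(nodes))^3
  tt[abs(v6) > 1e-12 * scale3, , drop = FALSE]
}

#' @noRd
tet_signed_volume6 <- function(tets, nodes) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  rowSums(vec3_cross(b, c_) * d)
}

#' Tetrahedron volumes of a mesh
#' @param mesh a `tet_mesh`.
#' @return numeric vector of volumes (mm^3), positive by construction.
#' @export
tet_volumes <- function(mesh) tet_signed_volume6(mesh$tets, mesh$nodes) / 6

# ---- boundary extraction -------------------------------------------------

# Boundary faces (appearing in exactly one tet), oriented outward.
#' @noRd
extract_boundary <- function(tets, nodes) {
  local_faces <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  fs <- rbind(tets[, local_faces[1, ]], tets[, local_faces[2, ]],
              tets[, local_faces[3, ]], tets[, local_faces[4, ]])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  key <- apply_sorted_key(fs)
  cnt <- table(key)
  bnd <- key %in% names(cnt)[cnt == 1L]
  fs <- fs[bnd, , drop = FALSE]
  opp <- opp[bnd]
  # enforce outward orientation against the opposite (interior) node
  a <- nodes[fs[, 1], , drop = FALSE]
  n <- vec3_cross(nodes[fs[, 2], , drop = FALSE] - a,
                  nodes[fs[, 3], , drop = FALSE] - a)
  inward <- rowSums(n * (nodes[opp, , drop = FALSE] - a)) > 0
  fs[inward, c(2, 3)] <- fs[inward, c(3, 2)]
  fs
}

#' @noRd
apply_sorted_key <- function(fs) {
  s1 <- pmin(fs[, 1], fs[, 2], fs[, 3])
  s3 <- pmax(fs[, 1], fs[, 2], fs[, 3])
  s2 <- fs[, 1] + fs[, 2] + fs[, 3] - s1 - s3
  paste(s1, s2, s3)
}

# ---- the biventricle builder --------------------------------------------

#' Build the idealized truncated-ellipsoid biventricular mesh
#'
#' Generates a labelled tetrahedral mesh: LV wall between two confocal-ish
#' truncated ellipsoids, RV free wall attached to the LV epicardium over an
#' angular window (the RV cavity is the unmeshed gap between them), and a
#' basal tissue band extruded above the truncation plane carrying VEIN_RING
#' labels on its upper rim. Boundary triangles are labelled LV_ENDO, RV_ENDO,
#' EPI or VEIN_RING; the basal closure of each cavity is provided virtually
#' by [cavity_closure()]. Deterministic given the parameters.
#'
#' @param params a [geometry_params()] object.
#' @return object of class `tet_mesh` with fields `nodes` (n x 3, mm), `tets`
#'   (m x 4), `tet_region` (LV_MYO/RV_MYO/BASAL_TISSUE), `boundary_tris`,
#'   `boundary_label`, `apex_patch`, `node_flags` and `params`.
#' @export
build_idealized_biventricle <- function(params = geometry_params()) {
  stopifnot(inherits(params, "geometry_params"))
  p <- params
  h <- p$edge_length
  c_en <- p$lv_length - p$trunc_height
  a_en <- p$lv_radius
  a_ep <- a_en + p$lv_thickness
  c_ep <- c_en + p$lv_thickness
  z_base <- p$lv_length
  phi_en <- acos(-p$trunc_height / c_en)
  phi_ep <- acos(-p$trunc_height / c_ep)

  # meridian arc length of the epicardial curve, for mu resolution
  tt <- seq(0, phi_ep, length.out = 200)
  xs <- a_ep * sin(tt); zs <- -c_ep * cos(tt)
  arc <- sum(sqrt(diff(xs)^2 + diff(zs)^2))
  n_mu <- max(6L, round(arc / h))
  n_th <- max(12L, round(2 * pi * (a_en + p$lv_thickness / 2) / h))
  # at least two transmural layers: a single layer samples only the midwall
  # helix angle (~circumferential) and misrepresents the contraction mode
  n_tau <- max(2L, round(p$lv_thickness / h))
  n_rv <- max(1L, round(p$rv_thickness / h))
  n_band <- max(1L, round(p$band_height / h))

  theta <- 2 * pi * (seq_len(n_th) - 1) / n_th
  mu <- seq(0, 1, length.out = n_mu + 1)
  tau <- seq(0, 1, length.out = n_tau + 1)

  # RV angular window on grid columns (theta centred on pi/2, the free wall)
  th_c <- pi / 2
  j1 <- which.min(abs(theta - (th_c - p$rv_span / 2)))
  j2 <- which.min(abs(theta - (th_c + p$rv_span / 2)))
  if (j2 - j1 < 3) stop("rv_span too small for this resolution")
  i_rv0 <- max(2L, floor(p$rv_apex_frac * n_mu))

  nmax <- (n_mu + 1) * n_th * (n_tau + 1) + (n_mu + 1) * n_th * (n_rv + 1) +
    (n_band + 1) * n_th * (n_tau + n_rv + 4)
  nodes <- matrix(NA_real_, nmax, 3)
  nn <- 0L
  new_node <- function(x, y, z) {
    nn <<- nn + 1L
    nodes[nn, ] <<- c(x, y, z)
    nn
  }

  # --- LV wall nodes ---
  lvid <- array(NA_integer_, c(n_mu + 1, n_th, n_tau + 1))
  for (i in seq_len(n_mu + 1)) {
    fe <- mu[i] * phi_en; fp <- mu[i] * phi_ep
    if (i == 1L) {
      for (k in seq_len(n_tau + 1)) {
        z <- (1 - tau[k]) * 0 + tau[k] * (-p$lv_thickness)
        id <- new_node(0, 0, z)
        lvid[1, , k] <- id
      }
    } else {
      pe_r <- a_en * sin(fe); pe_z <- c_en - c_en * cos(fe)
      pp_r <- a_ep * sin(fp); pp_z <- c_en - c_ep * cos(fp)
      for (j in seq_len(n_th)) {
        ct <- cos(theta[j]); st <- sin(theta[j])
        for (k in seq_len(n_tau + 1)) {
          r <- (1 - tau[k]) * pe_r + tau[k] * pp_r
          z <- (1 - tau[k]) * pe_z + tau[k] * pp_z
          lvid[i, j, k] <- new_node(r * ct, r * st, z)
        }
      }
    }
  }

  # --- RV free wall nodes ---
  # the gap (cavity width) is zero over attachment aprons at the window
  # edges and the RV apex, where the free wall is glued face-to-face onto
  # the LV epicardium; it opens smoothly in between
  gap <- matrix(0, n_mu + 1, n_th)
  jj <- j1:j2
  frac <- (jj - j1) / (j2 - j1)
  apron <- 0.15
  frac_in <- clamp((frac - apron) / (1 - 2 * apron), 0, 1)
  for (i in i_rv0:(n_mu + 1)) {
    ramp <- smoothstep((mu[i] - p$rv_apex_frac - 0.08) / 0.30)
    gap[i, jj] <- p$rv_gap * sin(pi * frac_in) * ramp
  }
  gap[gap < 1e-9 * p$rv_gap] <- 0   # snap round-off to an exact glue
  rvid <- array(NA_integer_, c(n_mu + 1, n_th, n_rv + 1))
  for (i in i_rv0:(n_mu + 1)) {
    fp <- mu[i] * phi_ep
    pp_r <- a_ep * sin(fp); pp_z <- c_en - c_ep * cos(fp)
    for (j in jj) {
      ct <- cos(theta[j]); st <- sin(theta[j])
      x <- pp_r * ct; y <- pp_r * st; z <- pp_z
      nrm <- c(x / a_ep^2, y / a_ep^2, (z - c_en) / c_ep^2)
      nrm <- nrm / sqrt(sum(nrm^2))
      g <- gap[i, j]
      for (m in seq_len(n_rv + 1)) {
        d <- g + (m - 1) / n_rv * p$rv_thickness
        if (m == 1L && g == 0) {
          rvid[i, j, 1] <- lvid[i, j, n_tau + 1]
        } else {
          rvid[i, j, m] <- new_node(x + d * nrm[1], y + d * nrm[2],
                                    z + d * nrm[3])
        }
      }
    }
  }

  # --- basal band: extrude every top-surface node upward ---
  top_ids <- unique(c(lvid[n_mu + 1, , ], rvid[n_mu + 1, , ]))
  top_ids <- top_ids[!is.na(top_ids)]
  dz <- p$band_height / n_band
  bandid <- matrix(NA_integer_, n_band, nn)  # bandid[l, base] = extruded id
  for (l in seq_len(n_band)) {
    for (b in top_ids) {
      bandid[l, b] <- new_node(nodes[b, 1], nodes[b, 2], z_base + l * dz)
    }
  }
  nodes <- nodes[seq_len(nn), , drop = FALSE]

  # --- hex cells ---
  hex_list <- list(); reg_list <- list()
  wrap <- function(j) ((j - 1L) %% n_th) + 1L
  # LV wall
  hl <- matrix(0L, n_mu * n_th * n_tau, 8); hc <- 0L
  for (i in seq_len(n_mu)) for (j in seq_len(n_th)) for (k in seq_len(n_tau)) {
    j2w <- wrap(j + 1L)
    hc <- hc + 1L
    hl[hc, ] <- c(lvid[i, j, k], lvid[i + 1, j, k], lvid[i + 1, j2w, k],
                  lvid[i, j2w, k], lvid[i, j, k + 1], lvid[i + 1, j, k + 1],
                  lvid[i + 1, j2w, k + 1], lvid[i, j2w, k + 1])
  }
  hex_list$lv <- hl; reg_list$lv <- rep("LV_MYO", hc)
  # RV wall
  hr <- matrix(0L, (n_mu + 1 - i_rv0) * (j2 - j1) * n_rv, 8); hc <- 0L
  for (i in i_rv0:n_mu) for (j in j1:(j2 - 1L)) for (m in seq_len(n_rv)) {
    hc <- hc + 1L
    hr[hc, ] <- c(rvid[i, j, m], rvid[i + 1, j, m], rvid[i + 1, j + 1, m],
                  rvid[i, j + 1, m], rvid[i, j, m + 1], rvid[i + 1, j, m + 1],
                  rvid[i + 1, j + 1, m + 1], rvid[i, j + 1, m + 1])
  }
  hex_list$rv <- hr[seq_len(hc), , drop = FALSE]
  reg_list$rv <- rep("RV_MYO", hc)
  # band: extrude LV top annulus quads and RV top annulus quads
  quads <- list(); qc <- 0L
  for (j in seq_len(n_th)) for (k in seq_len(n_tau)) {
    qc <- qc + 1L
    quads[[qc]] <- c(lvid[n_mu + 1, j, k], lvid[n_mu + 1, wrap(j + 1L), k],
                     lvid[n_mu + 1, wrap(j + 1L), k + 1], lvid[n_mu + 1, j, k + 1])
  }
  for (j in j1:(j2 - 1L)) for (m in seq_len(n_rv)) {
    qc <- qc + 1L
    quads[[qc]] <- c(rvid[n_mu + 1, j, m], rvid[n_mu + 1, j + 1, m],
                     rvid[n_mu + 1, j + 1, m + 1], rvid[n_mu + 1, j, m + 1])
  }
  quads <- do.call(rbind, quads)
  hb <- matrix(0L, nrow(quads) * n_band, 8); hc <- 0L
  lid <- function(l, b) if (l == 0L) b else bandid[l, b]
  for (l in seq_len(n_band)) {
    lo <- l - 1L
    for (q in seq_len(nrow(quads))) {
      hc <- hc + 1L
      qd <- quads[q, ]
      hb[hc, ] <- c(vapply(qd, function(b) lid(lo, b), 0L),
                    vapply(qd, function(b) lid(l, b), 0L))
    }
  }
  hex_list$band <- hb; reg_list$band <- rep("BASAL_TISSUE", hc)

  hex <- do.call(rbind, hex_list)
  regions <- unlist(reg_list, use.names = FALSE)
  # tetrahedralize, tracking the owner cell to carry region labels
  ncell <- nrow(hex)
  hex_tagged <- cbind(hex, seq_len(ncell))
  tets_by_cell <- hexes_to_tets_tagged(hex_tagged, nodes)
  tets <- tets_by_cell$tets
  tet_region <- regions[tets_by_cell$cell]

  # --- node flags ---
  flags <- matrix(FALSE, nn, 6,
                  dimnames = list(NULL, c("lv_endo", "lv_epi", "rv_endo",
                                          "rv_outer", "top", "basal")))
  flags[as.vector(lvid[, , 1]), "lv_endo"] <- TRUE
  flags[as.vector(lvid[, , n_tau + 1]), "lv_epi"] <- TRUE
  win <- as.vector(lvid[i_rv0:(n_mu + 1), j1:j2, n_tau + 1])
  flags[win, "rv_endo"] <- TRUE                      # septal cavity lining
  rv_in <- as.vector(rvid[, , 1]); rv_in <- rv_in[!is.na(rv_in)]
  flags[rv_in, "rv_endo"] <- TRUE                    # free-wall cavity lining
  rv_out <- as.vector(rvid[, , n_rv + 1]); rv_out <- rv_out[!is.na(rv_out)]
  flags[rv_out, "rv_outer"] <- TRUE
  # band nodes inherit the flags of their base node; top layer flagged
  for (l in seq_len(n_band)) {
    ids <- bandid[l, top_ids]
    flags[ids, ] <- flags[top_ids, ]
    flags[ids, "basal"] <- TRUE
    if (l == n_band) flags[ids, "top"] <- TRUE
  }

  bt <- extract_boundary(tets, nodes)
  lab <- classify_boundary(bt, flags)
  # omni-directional anchors act only at discrete cropped-vein patches on
  # the upper rim; the rest of the cut plane is a free surface (TOP)
  if (any(lab == "VEIN_RING")) {
    topf <- which(lab == "VEIN_RING")
    cen <- (nodes[bt[topf, 1], , drop = FALSE] +
              nodes[bt[topf, 2], , drop = FALSE] +
              nodes[bt[topf, 3], , drop = FALSE]) / 3
    r_mid <- mean(sqrt(cen[, 1]^2 + cen[, 2]^2))
    ang <- 2 * pi * (seq_len(p$vein_count) - 1) / p$vein_count + pi / 6
    keep <- rep(FALSE, length(topf))
    for (a in ang) {
      ctr <- c(r_mid * cos(a), r_mid * sin(a))
      keep <- keep | (sqrt((cen[, 1] - ctr[1])^2 +
                             (cen[, 2] - ctr[2])^2) <= p$vein_radius)
    }
    lab[topf[!keep]] <- "TOP"
  }

  # apex patch: nodes within apex_radius of the lowest epicardial point
  apex_pt <- nodes[which.min(nodes[, 3]), ]
  d <- sqrt(colSums((t(nodes) - apex_pt)^2))
  apex_patch <- which(d <= p$apex_radius)

  mesh <- structure(list(
    nodes = nodes, tets = tets, tet_region = tet_region,
    boundary_tris = bt, boundary_label = lab,
    apex_patch = apex_patch, node_flags = flags,
    long_axis = c(0, 0, 1), z_base = z_base, params = p), class = "tet_mesh")
  mesh
}

#' @noRd
hexes_to_tets_tagged <- function(hex_tagged, nodes) {
  hex <- hex_tagged[, 1:8, drop = FALSE]
  cell <- hex_tagged[, 9]
  faces_local <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                       c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  n <- nrow(hex)
  v0 <- hex[cbind(seq_len(n), max.col(-hex, ties.method = "first"))]
  tets <- vector("list", 6L); cells <- vector("list", 6L)
  for (fi in 1:6) {
    f <- hex[, faces_local[fi, ], drop = FALSE]
    has_v0 <- (f[, 1] == v0) | (f[, 2] == v0) | (f[, 3] == v0) | (f[, 4] == v0)
    k <- max.col(-f, ties.method = "first")
    idx <- function(off) f[cbind(seq_len(n), ((k - 1 + off) %% 4) + 1)]
    a <- idx(0); b <- idx(1); c_ <- idx(2); d <- idx(3)
    keep <- !has_v0
    tets[[fi]] <- rbind(cbind(v0, a, b, c_)[keep, , drop = FALSE],
                        cbind(v0, a, c_, d)[keep, , drop = FALSE])
    cells[[fi]] <- c(cell[keep], cell[keep])
  }
  tt <- do.call(rbind, tets)
  cc <- unlist(cells)
  dup <- (tt[, 1] == tt[, 2]) | (tt[, 1] == tt[, 3]) | (tt[, 1] == tt[, 4]) |
    (tt[, 2] == tt[, 3]) | (tt[, 2] == tt[, 4]) | (tt[, 3] == tt[, 4])
  tt <- tt[!dup, , drop = FALSE]; cc <- cc[!dup]
  dimnames(tt) <- NULL
  v6 <- tet_signed_volume6(tt, nodes)
  flip <- v6 < 0
  if (any(flip)) tt[flip, c(3, 4)] <- tt[flip, c(4, 3)]
  scale3 <- max(abs(nodes))^3
  keep <- abs(v6) > 1e-12 * scale3
  list(tets = tt[keep, , drop = FALSE], cell = cc[keep])
}

#' @noRd
classify_boundary <- function(bt, flags) {
  f3 <- function(col) flags[bt[, 1], col] & flags[bt[, 2], col] & flags[bt[, 3], col]
  lab <- rep("EPI", nrow(bt))
  lab[f3("lv_endo")] <- "LV_ENDO"
  lab[f3("rv_endo")] <- "RV_ENDO"
  lab[f3("top")] <- "VEIN_RING"
  lab
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$tet_region)),
                                  table(x$tet_region)), collapse = ", "), "\n")
  cat("  boundary:", paste(sprintf("%s=%d", names(table(x$boundary_label)),
                                   table(x$boundary_label)), collapse = ", "), "\n")
  invisible(x)
}

# ---- validation geometries ----------------------------------------------

#' Structured bar mesh (validation geometry)
#'
#' Axis-aligned box split into tetrahedra, used to validate the eikonal
#' solver against one-dimensional closed forms and the wall-coordinate
#' solver against the linear harmonic profile on a prism.
#'
#' @param lx,ly,lz box dimensions (mm).
#' @param h target edge length (mm).
#' @return a `tet_mesh` with region `LV_MYO` and all boundary labelled `EPI`.
#' @export
build_bar_mesh <- function(lx, ly, lz, h) {
  nx <- max(1L, round(lx / h)); ny <- max(1L, round(ly / h))
  nz <- max(1L, round(lz / h))
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  id <- array(seq_len((nx + 1) * (ny + 1) * (nz + 1)),
              c(nx + 1, ny + 1, nz + 1))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  hex <- matrix(0L, nx * ny * nz, 8); hc <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    hc <- hc + 1L
    hex[hc, ] <- c(id[i, j, k], id[i + 1, j, k], id[i + 1, j + 1, k],
                   id[i, j + 1, k], id[i, j, k + 1], id[i + 1, j, k + 1],
                   id[i + 1, j + 1, k + 1], id[i, j + 1, k + 1])
  }
  tets <- hexes_to_tets(hex, nodes)
  bt <- extract_boundary(tets, nodes)
  structure(list(nodes = nodes, tets = tets,
                 tet_region = rep("LV_MYO", nrow(tets)),
                 boundary_tris = bt, boundary_label = rep("EPI", nrow(bt)),
                 apex_patch = integer(0),
                 node_flags = matrix(FALSE, nrow(nodes), 0),
                 long_axis = c(0, 0, 1), z_base = lz,
                 params = list(edge_length = h)), class = "tet_mesh")
}

#' Spherical shell mesh (validation geometry)
#'
#' Closed thick spherical shell used to validate the mechanics solver against
#' the Lame thick-shell inflation solution. Inner boundary is labelled
#' `LV_ENDO`, outer `EPI`; region is `BASAL_TISSUE` (neo-Hookean by default).
#'
#' @param r_in,r_out inner and outer radii (mm).
#' @param h target edge length (mm).
#' @return a `tet_mesh`.
#' @export
build_spherical_shell <- function(r_in, r_out, h) {
  n_phi <- max(6L, round(pi * r_out / h))
  n_th <- max(8L, round(2 * pi * r_out / h))
  n_tau <- max(2L, round((r_out - r_in) / h) + 1L)
  phi <- seq(0, pi, length.out = n_phi + 1)
  theta <- 2 * pi * (seq_len(n_th) - 1) / n_th
  rr <- seq(r_in, r_out, length.out = n_tau + 1)
  nodes <- matrix(NA_real_, (n_phi + 1) * n_th * (n_tau + 1), 3)
  id <- array(NA_integer_, c(n_phi + 1, n_th, n_tau + 1)); nn <- 0L
  for (i in seq_len(n_phi + 1)) for (j in seq_len(n_th)) {
    if ((i == 1L || i == n_phi + 1L) && j > 1L) {
      id[i, j, ] <- id[i, 1, ]
      next
    }
    sp <- sin(phi[i]); cp <- cos(phi[i])
    for (k in seq_len(n_tau + 1)) {
      nn <- nn + 1L
      nodes[nn, ] <- rr[k] * c(sp * cos(theta[j]), sp * sin(theta[j]), cp)
      id[i, j, k] <- nn
    }
  }
  nodes <- nodes[seq_len(nn), , drop = FALSE]
  wrap <- function(j) ((j - 1L) %% n_th) + 1L
  hex <- matrix(0L, n_phi * n_th * n_tau, 8); hc <- 0L
  for (i in seq_len(n_phi)) for (j in seq_len(n_th)) for (k in seq_len(n_tau)) {
    hc <- hc + 1L
    jp <- wrap(j + 1L)
    hex[hc, ] <- c(id[i, j, k], id[i + 1, j, k], id[i + 1, jp, k],
                   id[i, jp, k], id[i, j, k + 1], id[i + 1, j, k + 1],
                   id[i + 1, jp, k + 1], id[i, jp, k + 1])
  }
  tets <- hexes_to_tets(hex, nodes)
  bt <- extract_boundary(tets, nodes)
  rad <- sqrt(rowSums(nodes^2))
  inner <- rad[bt[, 1]] < (r_in + r_out) / 2 &
    rad[bt[, 2]] < (r_in + r_out) / 2 & rad[bt[, 3]] < (r_in + r_out) / 2
  structure(list(nodes = nodes, tets = tets,
                 tet_region = rep("BASAL_TISSUE", nrow(tets)),
                 boundary_tris = bt,
                 boundary_label = ifelse(inner, "LV_ENDO", "EPI"),
                 apex_patch = integer(0),
                 node_flags = matrix(FALSE, nrow(nodes), 0),
                 long_axis = c(0, 0, 1), z_base = r_out,
                 params = list(edge_length = h)), class = "tet_mesh")
}

# ---- surfaces and cavity closure ----------------------------------------

# per-node outward unit normals and lumped areas (one third of adjacent
# triangle areas) over boundary faces with the given labels, on the
# reference configuration
#' @noRd
surface_node_weights <- function(mesh, labels) {
  sel <- mesh$boundary_label %in% labels
  tris <- mesh$boundary_tris[sel, , drop = FALSE]
  a <- mesh$nodes[tris[, 1], , drop = FALSE]
  n2 <- vec3_cross(mesh$nodes[tris[, 2], , drop = FALSE] - a,
                   mesh$nodes[tris[, 3], , drop = FALSE] - a)  # 2*area*normal
  area <- vec3_norm(n2) / 2
  ids <- as.vector(tris)
  w <- rep(area / 3, 3)
  nrm_contrib <- rbind(n2, n2, n2) / 2
  uid <- sort(unique(ids))
  idx <- match(ids, uid)
  areas <- rowsum_by(matrix(w), idx, length(uid))[, 1]
  nrms <- rowsum_by(nrm_contrib, idx, length(uid))
  list(nodes = uid, area = areas, normal = vec3_normalize(nrms))
}

#' Cavity closure of a labelled endocardial surface
#'
#' Collects the boundary triangles of one cavity, re-orients them so normals
#' point out of the cavity, and closes the basal orifice with a virtual
#' centroid fan over the rim loop. The centroid tracks the deformed rim, so
#' the closure is a smooth function of the displacement field.
#'
#' @param mesh a `tet_mesh`.
#' @param cavity `"LV"` or `"RV"`.
#' @return list with `tris` (cavity-outward triangles), `rim` (ordered rim
#'   node ids, possibly empty for an already-closed surface) and `cap_edges`
#'   (directed rim edges for the fan).
#' @export
cavity_closure <- function(mesh, cavity = c("LV", "RV")) {
  cavity <- match.arg(cavity)
  lab <- paste0(cavity, "_ENDO")
  tris <- mesh$boundary_tris[mesh$boundary_label == lab, , drop = FALSE]
  if (nrow(tris) == 0) stop("no boundary triangles labelled ", lab)
  tris <- tris[, c(1, 3, 2), drop = FALSE]  # flip: outward of the cavity
  ed <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  open_e <- ed[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  # cap triangles continue the surface orientation: (a, b, centroid)
  rim <- unique(as.vector(open_e))
  cl <- list(tris = tris, rim = rim, cap_edges = open_e)
  # precomputed scatter map for the volume gradient
  ids <- c(tris[, 1], tris[, 2], tris[, 3])
  if (length(rim) > 0) ids <- c(ids, open_e[, 2], open_e[, 1], rim)
  cl$grad_uid <- sort(unique(ids))
  cl$grad_map <- match(ids, cl$grad_uid)
  cl
}

#' Cavity volume from the deformed configuration
#'
#' Divergence-theorem volume of the closed cavity surface (endocardial
#' triangles plus virtual basal fan cap), exact for affine elements.
#'
#' @param mesh a `tet_mesh`.
#' @param cavity `"LV"` or `"RV"`, or a precomputed [cavity_closure()].
#' @param u optional n x 3 nodal displacement field (mm); 0 if missing.
#' @return volume in mL (1 mL = 1000 mm^3).
#' @export
cavity_volume <- function(mesh, cavity = "LV", u = NULL) {
  cl <- if (is.list(cavity) && !is.null(cavity$tris)) cavity
        else cavity_closure(mesh, cavity)
  x <- mesh$nodes
  if (!is.null(u)) x <- x + u
  v <- closed_surface_volume6(cl, x) / 6
  if (v <= 0) stop("non-positive cavity volume: surface misoriented or open")
  v / 1000
}

#' @noRd
closed_surface_volume6 <- function(cl, x) {
  tr <- cl$tris
  a <- x[tr[, 1], , drop = FALSE]
  b <- x[tr[, 2], , drop = FALSE]
  c_ <- x[tr[, 3], , drop = FALSE]
  v <- sum(rowSums(vec3_cross(a, b) * c_))
  if (length(cl$rim) > 0) {
    ctr <- colMeans(x[cl$rim, , drop = FALSE])
    # cap triangles (b, a, centroid): opposite edge direction closes the
    # oriented surface consistently
    ea <- x[cl$cap_edges[, 2], , drop = FALSE]
    eb <- x[cl$cap_edges[, 1], , drop = FALSE]
    v <- v + sum(rowSums(vec3_cross(ea, eb) *
                           matrix(ctr, nrow(ea), 3, byrow = TRUE)))
  }
  v
}

# gradient of (6 * volume) with respect to nodal coordinates, returned as a
# sparse triplet accumulation over the n x 3 coordinate array
#' @noRd
closed_surface_volume6_grad <- function(cl, x, nn) {
  tr <- cl$tris
  a <- x[tr[, 1], , drop = FALSE]
  b <- x[tr[, 2], , drop = FALSE]
  c_ <- x[tr[, 3], , drop = FALSE]
  ga <- vec3_cross(b, c_); gb <- vec3_cross(c_, a); gc <- vec3_cross(a, b)
  vals <- rbind(ga, gb, gc)
  if (length(cl$rim) > 0) {
    ctr <- colMeans(x[cl$rim, , drop = FALSE])
    ea <- x[cl$cap_edges[, 2], , drop = FALSE]
    eb <- x[cl$cap_edges[, 1], , drop = FALSE]
    ctrm <- matrix(ctr, nrow(ea), 3, byrow = TRUE)
    g1 <- vec3_cross(eb, ctrm)
    g2 <- vec3_cross(ctrm, ea)
    gctr <- colSums(vec3_cross(ea, eb))
    vals <- rbind(vals, g1, g2,
                  matrix(gctr / length(cl$rim), length(cl$rim), 3, byrow = TRUE))
  }
  g <- matrix(0, nn, 3)
  acc <- rowsum_by(vals, cl$grad_map, length(cl$grad_uid))
  g[cl$grad_uid, ] <- acc
  g
}
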