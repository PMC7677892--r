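# The pericardial boundary-condition machinery: derive an apico-basal
# spring-stiffness scaling (penalty map) from the epicardial
# normal-displacement profile of the target motion, and evaluate the Robin
# normal-spring and omni-directional vein-spring tractions.

#' Spring boundary-condition parameters
#' @param k_vein omni-directional spring stiffness on the VEIN_RING boundary
#'   (kPa/mm).
#' @param pericardium logical: apply epicardial normal springs?
#' @param k_uniform optional uniform normal-spring stiffness override
#'   (kPa/mm) replacing the penalty map scaling.
#' @export
spring_bc_params <- function(k_vein = 10, pericardium = TRUE,
                             k_uniform = NULL) {
  stopifnot(k_vein >= 0, is.null(k_uniform) || k_uniform >= 0)
  structure(list(k_vein = k_vein, pericardium = pericardium,
                 k_uniform = k_uniform), class = "spring_bc_params")
}

#' Derive the apico-basal penalty map from epicardial motion
#'
#' Implements the normalize-then-flip construction: epicardial nodes are
#' binned by the apico-basal coordinate `xi`, the mean normal displacement
#' per bin is normalized to `[0, 1]`, fitted with a monotone non-decreasing
#' function (isotonic regression on the bin means followed by a monotone
#' cubic interpolant), and flipped: `scale(xi) = 1 - g(xi)`. Regions that
#' move least normal to the surface (the apex) therefore carry maximum
#' penalty, and the most mobile basal epicardium carries none.
#'
#' @param epi_normal_disp per-epicardial-node normal displacement (mm), as
#'   from [extract_epicardial_normal_displacement()] (a list with `nodes`
#'   and `value`), or a bare numeric vector aligned with `xi`.
#' @param xi apico-basal coordinate: full per-node vector when
#'   `epi_normal_disp` is a list, else aligned with the displacement vector.
#' @param n_bins number of equal-width xi bins.
#' @param k_max maximum normal-spring stiffness (kPa/mm).
#' @return object of class `penalty_map` with the scaling function and fit
#'   metadata.
#' @export
derive_penalty_map <- function(epi_normal_disp, xi, n_bins = 20, k_max = 50) {
  if (is.list(epi_normal_disp)) {
    d <- epi_normal_disp$value
    x <- xi[epi_normal_disp$nodes]
  } else {
    d <- epi_normal_disp
    x <- xi
  }
  stopifnot(length(d) == length(x), n_bins >= 2, k_max >= 0)
  if (length(unique(d)) < 2 || diff(range(d)) < 1e-12)
    stop("degenerate normalization: epicardial displacement has no range")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- clamp(findInterval(x, edges, rightmost.closed = TRUE), 1, n_bins)
  Dm <- tapply(d, factor(bin, levels = seq_len(n_bins)), mean)
  ctr <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  keep <- !is.na(Dm)
  ctr <- ctr[keep]; Dm <- as.numeric(Dm[keep])
  if (diff(range(Dm)) < 1e-12)
    stop("degenerate normalization: binned displacement profile is constant")
  Dn <- (Dm - min(Dm)) / (max(Dm) - min(Dm))
  iso <- stats::isoreg(ctr, Dn)
  yfit <- iso$yf
  # monotone cubic through the isotonic bin means, pinned to the xi extremes
  xs <- c(0, ctr, 1)
  ys <- c(yfit[1], yfit, yfit[length(yfit)])
  dupx <- duplicated(xs)
  fun_g <- stats::splinefun(xs[!dupx], ys[!dupx], method = "hyman")
  scale_fun <- function(x) clamp(1 - fun_g(clamp(x, 0, 1)), 0, 1)
  structure(list(scale = scale_fun, k_max = k_max,
                 bin_centers = ctr, bin_means = Dm, bin_norm = Dn,
                 iso_fit = yfit, n_bins = n_bins), class = "penalty_map")
}

#' Uniform penalty map (constant scaling 1)
#' @param k_max the uniform normal-spring stiffness (kPa/mm).
#' @export
uniform_penalty_map <- function(k_max = 50) {
  structure(list(scale = function(x) rep(1, length(x)), k_max = k_max,
                 bin_centers = numeric(0), bin_means = numeric(0),
                 bin_norm = numeric(0), iso_fit = numeric(0), n_bins = 0L),
            class = "penalty_map")
}

#' @export
print.penalty_map <- function(x, ...) {
  cat("penalty_map: k_max =", x$k_max, "kPa/mm; scale(0) =",
      round(x$scale(0), 3), ", scale(1) =", round(x$scale(1), 3), "\n")
  invisible(x)
}

#' Normal-spring stiffness at an apico-basal position
#'
#' `k_n = k_max * scale(xi)`; values of `xi` outside `[0, 1]` are clamped
#' with a warning.
#' @param map a `penalty_map`.
#' @param xi apico-basal coordinate(s).
#' @export
stiffness_at <- function(map, xi) {
  if (any(xi < 0 | xi > 1)) {
    warning("xi outside [0, 1] clamped")
    xi <- clamp(xi, 0, 1)
  }
  map$k_max * map$scale(xi)
}

#' Robin normal-spring traction
#'
#' `t = -k_n (u . n0) n0`: purely normal, evaluated against the reference
#' (ED) outward normal, so tangential sliding on the pericardium is free.
#' @param u displacement (mm): 3-vector or n x 3 matrix.
#' @param n0 reference outward unit normal(s), same shape.
#' @param k_n normal stiffness (kPa/mm), scalar or per-row.
#' @return traction (kPa), same shape as `u`.
#' @export
robin_normal_traction <- function(u, n0, k_n) {
  if (is.null(dim(u))) {
    stopifnot(abs(sum(n0^2) - 1) < 1e-8)
    return(-k_n * sum(u * n0) * n0)
  }
  -k_n * rowSums(u * n0) * n0
}

#' Omni-directional spring traction
#'
#' `t = -k u`, the vein-ring anchoring traction.
#' @param u displacement (mm): 3-vector or n x 3 matrix.
#' @param k_vein stiffness (kPa/mm).
#' @export
omni_spring_traction <- function(u, k_vein) -k_vein * u

# ---- assembled nodal spring model ---------------------------------------

# Lumped nodal springs: traction (kPa) times one third of adjacent reference
# triangle area per node gives force. Returns a structure used by the
# mechanics energy/gradient.
#' @noRd
build_spring_model <- function(mesh, coords, bc, map = NULL) {
  model <- list()
  if (bc$k_vein > 0 && any(mesh$boundary_label == "VEIN_RING")) {
    sw <- surface_node_weights(mesh, "VEIN_RING")
    model$vein <- list(nodes = sw$nodes, kA = bc$k_vein * sw$area)
  }
  if (isTRUE(bc$pericardium)) {
    sw <- surface_node_weights(mesh, "EPI")
    k_n <- if (!is.null(bc$k_uniform)) rep(bc$k_uniform, length(sw$nodes))
           else {
             if (is.null(map)) stop("pericardium enabled but no penalty map")
             stiffness_at(map, clamp(coords$xi[sw$nodes], 0, 1))
           }
    model$peri <- list(nodes = sw$nodes, n0 = sw$normal, kA = k_n * sw$area)
  }
  model
}

# energy (kPa mm^3) and gradient (kPa mm^2 per node) of the spring model
#' @noRd
spring_energy_grad <- function(model, u, grad = TRUE) {
  e <- 0
  g <- if (grad) matrix(0, nrow(u), 3) else NULL
  if (!is.null(model$vein)) {
    uu <- u[model$vein$nodes, , drop = FALSE]
    e <- e + 0.5 * sum(model$vein$kA * rowSums(uu * uu))
    if (grad) g[model$vein$nodes, ] <- g[model$vein$nodes, ] +
        model$vein$kA * uu
  }
  if (!is.null(model$peri)) {
    uu <- u[model$peri$nodes, , drop = FALSE]
    un <- rowSums(uu * model$peri$n0)
    e <- e + 0.5 * sum(model$peri$kA * un^2)
    if (grad) g[model$peri$nodes, ] <- g[model$peri$nodes, ] +
        (model$peri$kA * un) * model$peri$n0
  }
  list(energy = e, grad = g)
}
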