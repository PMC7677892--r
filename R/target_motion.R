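# Synthetic systolic target motion: the data product of gated-CT motion
# tracking (ten frames of per-node displacement relative to end-diastole),
# with the structure the pericardium analysis assumes -- large basal
# descent, a nearly static apex, epicardial normal displacement growing
# from apex to base, and transmural wall thickening.

#' Parameters of the synthetic target motion
#'
#' @param avpd amplitude of basal (atrioventricular plane) descent (mm,
#'   positive down).
#' @param apex_drift apical displacement amplitude (mm).
#' @param normal_amp amplitude of the epicardial normal-displacement profile
#'   (mm).
#' @param normal_profile monotone function of the apico-basal coordinate
#'   `xi` in `[0, 1]` shaping the normal displacement (default identity).
#' @param thickening wall-thickening fraction at peak (dimensionless).
#' @param t_sys systole duration spanned by the frames (ms).
#' @param n_frames number of frames including the zero-displacement ED frame.
#' @param peak_frac fraction of `t_sys` at which displacement peaks; frames
#'   after it partially return toward ED.
#' @param noise_sd isotropic Gaussian jitter on nodal displacements (mm).
#' @param seed RNG seed recorded in the output metadata.
#' @export
target_motion_params <- function(avpd = 12, apex_drift = 1, normal_amp = 6,
                                 normal_profile = function(xi) xi,
                                 thickening = 0.15, t_sys = 300,
                                 n_frames = 10, peak_frac = 0.8,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(avpd >= 0, apex_drift >= 0, normal_amp >= 0, thickening >= 0,
            t_sys > 0, n_frames >= 2, noise_sd >= 0)
  structure(list(avpd = avpd, apex_drift = apex_drift,
                 normal_amp = normal_amp, normal_profile = normal_profile,
                 thickening = thickening, t_sys = t_sys,
                 n_frames = n_frames, peak_frac = peak_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "target_motion_params")
}

# smooth 0 -> 1 -> partial-return systolic time course on x in [0, 1]
#' @noRd
systolic_time_course <- function(x, peak_frac, return_frac = 0.25) {
  ifelse(x <= peak_frac,
         sin(pi / 2 * x / peak_frac)^2,
         1 - return_frac * (1 - cos(pi * (x - peak_frac) / (1 - peak_frac))) / 2)
}

#' Generate the synthetic target motion
#'
#' Analytic displacement field
#' `u(X, t) = s(t) [axial descent ~ xi + apical drift ~ (1 - xi) +
#' normal component with amplitude profile(xi) + transmural thickening]`
#' plus seeded Gaussian jitter; `s(t)` is a smooth 0 -> 1 -> partial-return
#' systolic time course and frame 0 is identically zero. The normal
#' component uses the reference outward surface normal on epicardial nodes
#' and the transmural direction (gradient of `tau`) in the interior, so the
#' extracted epicardial normal displacement reproduces
#' `normal_amp * profile(xi)` exactly at zero noise.
#'
#' @param mesh a `tet_mesh`.
#' @param coords a `wall_coords`.
#' @param params a [target_motion_params()].
#' @return object of class `motion_target`: list with `frames` (list of
#'   n x 3 displacement matrices, mm), `frame_times` (ms) and `params`.
#' @export
generate_target_motion <- function(mesh, coords, params = target_motion_params()) {
  p <- params
  n <- nrow(mesh$nodes)
  xi <- coords$xi; tau <- coords$tau
  la <- mesh$long_axis

  # interior transmural direction from grad(tau), averaged to nodes;
  # overridden by the true surface normal on epicardial nodes
  sd <- tet_shape_data(mesh)
  gt <- sd$grads[[1]] * tau[mesh$tets[, 1]] +
    sd$grads[[2]] * tau[mesh$tets[, 2]] +
    sd$grads[[3]] * tau[mesh$tets[, 3]] +
    sd$grads[[4]] * tau[mesh$tets[, 4]]
  nhat <- vec3_normalize(node_average_from_elements(mesh, vec3_normalize(gt),
                                                    seq_len(nrow(mesh$tets))))
  sw <- surface_node_weights(mesh, "EPI")
  nhat[sw$nodes, ] <- sw$normal

  prof <- p$normal_profile(xi)
  axial <- -p$avpd * xi + p$apex_drift * (1 - xi)^4
  u_shape <- outer(axial, la) -
    p$normal_amp * prof * nhat +
    p$thickening * mesh$params$lv_thickness * (tau - 0.5) * nhat

  ts <- seq(0, p$t_sys, length.out = p$n_frames)
  s <- systolic_time_course(ts / p$t_sys, p$peak_frac)
  s[1] <- 0
  set.seed(p$seed)
  frames <- vector("list", p$n_frames)
  for (k in seq_len(p$n_frames)) {
    uf <- s[k] * u_shape
    if (k > 1L && p$noise_sd > 0)
      uf <- uf + matrix(stats::rnorm(3 * n, sd = p$noise_sd), n, 3)
    frames[[k]] <- uf
  }
  structure(list(frames = frames, frame_times = ts,
                 time_course = s, params = p), class = "motion_target")
}

#' @export
print.motion_target <- function(x, ...) {
  pk <- which.max(x$time_course)
  cat("motion_target:", length(x$frames), "frames over",
      max(x$frame_times), "ms; peak |u| =",
      round(max(vec3_norm(x$frames[[pk]])), 2), "mm\n")
  invisible(x)
}

#' Frame index of peak displacement (end-systole of the target)
#' @param motion a `motion_target`.
#' @export
peak_frame <- function(motion) which.max(motion$time_course)

#' Interpolate the target displacement at a fraction of systole
#'
#' `frac = 0` is ED, `frac = 1` the peak-displacement frame; linear
#' interpolation in time between stored frames.
#' @param motion a `motion_target`.
#' @param frac fraction in `[0, 1]` (values beyond 1 continue into the
#'   partial-return tail).
#' @return n x 3 displacement matrix (mm).
#' @export
target_at_fraction <- function(motion, frac) {
  tp <- motion$frame_times[peak_frame(motion)]
  t_q <- clamp(frac, 0, max(motion$frame_times) / tp) * tp
  ts <- motion$frame_times
  k <- findInterval(t_q, ts, rightmost.closed = TRUE)
  k <- clamp(k, 1, length(ts) - 1)
  a <- (t_q - ts[k]) / (ts[k + 1] - ts[k])
  (1 - a) * motion$frames[[k]] + a * motion$frames[[k + 1]]
}

#' Epicardial normal displacement during systole
#'
#' Per-epicardial-node maximum over systolic frames of the unsigned normal
#' component `|u . n0|`, with `n0` the outward unit normal of the ED
#' configuration.
#'
#' @param mesh a `tet_mesh`.
#' @param motion a `motion_target`, or a list of displacement fields.
#' @return list with `nodes` (EPI node ids), `value` (mm, nonnegative) and
#'   `normal` (the reference normals used).
#' @export
extract_epicardial_normal_displacement <- function(mesh, motion) {
  if (!any(mesh$boundary_label == "EPI")) stop("mesh has no EPI labels")
  sw <- surface_node_weights(mesh, "EPI")
  frames <- if (inherits(motion, "motion_target")) motion$frames else motion
  val <- numeric(length(sw$nodes))
  for (uf in frames) {
    comp <- abs(rowSums(uf[sw$nodes, , drop = FALSE] * sw$normal))
    val <- pmax(val, comp)
  }
  list(nodes = sw$nodes, value = val, normal = sw$normal)
}
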